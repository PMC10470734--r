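#!/usr/bin/env Rscript
# Step 3: three-factor ordination.
#
# Principal component analysis of (motif presence, RdRp length, %UGA) over
# the classified panel plus a slice of the survey set, asking whether the
# large class separates from normal mitoviruses on PC1 the way the
# screening rule says it should.

library(mitoscreen)

panel <- read_metadata("results/02_panel_classification.tsv",
                       required = "genome_id")
survey <- read_metadata("results/02_survey_classification.tsv",
                        required = "genome_id")
survey <- survey[1:20, ]
survey$genome_id <- paste0("survey_", survey$genome_id)
fx <- rbind(panel[names(survey)], survey)

pca <- feature_pca(fx, k = 2)
scores <- data.frame(genome_id = rownames(pca$scores),
                     PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
                     label = fx$label[match(rownames(pca$scores),
                                            fx$genome_id)])
write_tsv(scores, "results/03_pca_scores.tsv")
write_tsv(data.frame(factor = rownames(pca$loadings), pca$loadings),
          "results/03_pca_loadings.tsv")

cat("explained variance:",
    paste(round(pca$explained_variance, 3), collapse = ", "), "\n")
lg <- scores$PC1[scores$label == "LARGE_DUAMITOVIRUS"]
nm <- scores$PC1[scores$label == "OTHER"]
sep <- min(lg) > max(nm) || min(nm) > max(lg)
cat("PC1 separates classes with zero overlap:", sep, "\n")
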
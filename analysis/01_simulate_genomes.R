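#!/usr/bin/env Rscript
# Step 1: simulate the study inputs.
#
# Generates (i) a seed alignment of the conserved N-terminal motif, (ii) a
# 14-genome panel of mitovirus-like genomes -- 8 "large" (RdRp ~1,036 aa,
# motif embedded, UGA-for-Trp rate 1.4%) and 6 "normal" (RdRp ~761 aa, no
# motif, UGA common) -- and (iii) a 415-genome large-class survey panel,
# with full ground truth. Everything downstream works only from the files
# written here.

library(mitoscreen)

seed <- 1L
dir.create("results", showWarnings = FALSE)

ms <- gen_motif_seed(seed = seed)
write_fasta(ms$alignment, "results/01_motif_seed.afa")
writeLines(ms$consensus, "results/01_motif_consensus.txt")

panel <- gen_genomes(n_large = 8, n_normal = 6, motif = ms$consensus,
                     seed = seed + 3L)
write_fasta(panel$genomes, "results/01_panel_genomes.fasta")
write_tsv(panel$truth, "results/01_panel_truth.tsv")

survey <- gen_genomes(n_large = 415, n_normal = 0, motif = ms$consensus,
                      seed = seed + 4L)
write_fasta(survey$genomes, "results/01_survey_genomes.fasta")
write_tsv(survey$truth, "results/01_survey_truth.tsv")

refset <- gen_reference_set(n_refs = 105, n_families = 3, family_size = 5,
                            seed = seed + 1L)
write_fasta(refset$refs, "results/01_reference_proteins.fasta")
write_tsv(refset$labels, "results/01_reference_labels.tsv")

cat("panel:", length(panel$genomes), "genomes;",
    sum(panel$truth$class == "large"), "large /",
    sum(panel$truth$class == "normal"), "normal\n")
cat("survey:", length(survey$genomes), "large-class genomes\n")
cat("references:", length(refset$refs), "labelled proteins\n")
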
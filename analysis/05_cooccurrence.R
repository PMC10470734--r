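#!/usr/bin/env Rscript
# Step 5: per-library co-occurrence.
#
# Tests whether large-duamitovirus counts track other-mitovirus counts
# across the 184 simulated libraries (Pearson correlation, Student's t),
# the habitat-overlap question the community simulation plants at
# rho = 0.6.

library(mitoscreen)

lc <- read_metadata("results/04_library_counts.tsv",
                    required = c("library_id", "n_large", "n_other"))
ct <- pearson_test(lc$n_large, lc$n_other)
out <- data.frame(r = ct$r, t_stat = ct$t_stat, df = ct$df,
                  p_two_sided = ct$p_two_sided, n = ct$n)
write_tsv(out, "results/05_cooccurrence.tsv")
cat(sprintf("r = %.3f, t(%d) = %.2f, P = %.3g over %d libraries\n",
            ct$r, ct$df, ct$t_stat, ct$p_two_sided, ct$n))
cat("positively correlated at P < 0.001:", ct$p_two_sided < 0.001, "\n")
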
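test_that("%UGA is computed on the Trp denominator", {
  codons <- c(rep("UGA", 3), rep("UGG", 7), "GCA", "AAA")
  u <- trp_codon_usage(codons)
  expect_equal(u$uga_pct, 30)
  expect_identical(u$n_trp, 10L)

  all_ugg <- trp_codon_usage(c("AUG", "UGG", "UGG"))
  expect_equal(all_ugg$uga_pct, 0)

  no_trp <- trp_codon_usage(c("AUG", "GCA"))
  expect_true(is.na(no_trp$uga_pct))
  expect_identical(no_trp$n_trp, 0L)

  expect_error(trp_codon_usage(c("UGA", "GCA"), "MA"),
               "inconsistency")
  expect_error(trp_codon_usage(c("UGA"), "WW"), "mismatch")
})

test_that("%UGA estimate falls in the binomial CI of the planted rate", {
  # per-Trp UGA probability 0.65 with n_trp = 60
  set.seed(77)
  codons <- ifelse(runif(60) < 0.65, "UGA", "UGG")
  u <- trp_codon_usage(codons)
  ci <- stats::binom.test(round(u$uga_pct / 100 * 60), 60,
                          p = 0.65, conf.level = 0.99)
  expect_gt(ci$p.value, 0.01)
})

test_that("feature extraction recovers planted class structure", {
  ms <- gen_motif_seed(seed = 14)
  prof <- build_profile(ms$alignment)
  prof$threshold <- calibrate_threshold(prof, fpr = 1e-4, n_samples = 500,
                                        seed = 15)
  sim <- gen_genomes(n_large = 3, n_normal = 3, motif = ms$consensus,
                     seed = 16)
  fx <- extract_features_all(sim$genomes, prof)
  expect_identical(fx$motif_present, sim$truth$class == "large")
  expect_identical(fx$rdrp_len_aa, sim$truth$length_aa)
  expect_equal(fx$n_trp, sim$truth$n_trp)
  expect_equal(fx$uga_pct, 100 * sim$truth$n_uga / sim$truth$n_trp)
  # too short for any ORF at the minimum length -> no-RdRp error
  expect_error(extract_features("AUGGCAUAA", "tiny", prof),
               "no candidate RdRp")
})

test_that("the large-duamitovirus rule has an inclusive 900 aa boundary", {
  fv <- data.frame(genome_id = c("a", "b", "c", "d"),
                   motif_present = c(TRUE, TRUE, FALSE, FALSE),
                   rdrp_len_aa = c(900L, 899L, 1200L, 800L))
  cl <- classify(fv)
  expect_identical(cl$label,
                   c("LARGE_DUAMITOVIRUS", "OTHER", "OTHER", "OTHER"))
  expect_match(cl$reasons[2], "shorter than 900")
  expect_match(cl$reasons[3], "no N-terminal motif")
  expect_identical(cl$reasons[1], "")
})

test_that("classification is monotone in length and motif presence", {
  set.seed(18)
  for (rep in 1:50) {
    len <- sample(500:1200, 1)
    motif <- sample(c(TRUE, FALSE), 1)
    base <- classify(data.frame(genome_id = "x", motif_present = motif,
                                rdrp_len_aa = len))$label
    longer <- classify(data.frame(genome_id = "x", motif_present = motif,
                                  rdrp_len_aa = len + sample(1:300, 1)))$label
    with_motif <- classify(data.frame(genome_id = "x", motif_present = TRUE,
                                      rdrp_len_aa = len))$label
    if (base == "LARGE_DUAMITOVIRUS") {
      expect_identical(longer, "LARGE_DUAMITOVIRUS")
      expect_identical(with_motif, "LARGE_DUAMITOVIRUS")
    }
  }
})

test_that("PCA explained variances equal the correlation-matrix eigenvalues", {
  set.seed(19)
  for (rep in 1:25) {
    fx <- data.frame(genome_id = sprintf("g%02d", 1:50),
                     motif_present = runif(50) < 0.4,
                     rdrp_len_aa = sample(500:1200, 50, replace = TRUE),
                     uga_pct = runif(50, 0, 75))
    pca <- feature_pca(fx, k = 3)
    X <- cbind(as.numeric(fx$motif_present), fx$rdrp_len_aa, fx$uga_pct)
    ev <- eigen(stats::cor(X), symmetric = TRUE)$values
    expect_equal(pca$explained_variance, ev, tolerance = 1e-8)
    expect_lte(sum(pca$explained_variance), 3 + 1e-8)
    # loadings orthonormal
    expect_equal(crossprod(pca$loadings), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("PCA is deterministic over duplicates and row permutation", {
  set.seed(23)
  fx <- data.frame(genome_id = sprintf("g%02d", 1:12),
                   motif_present = rep(c(TRUE, FALSE), 6),
                   rdrp_len_aa = sample(600:1100, 12),
                   uga_pct = runif(12, 0, 60))
  fx$rdrp_len_aa[2] <- fx$rdrp_len_aa[1]
  fx$motif_present[2] <- fx$motif_present[1]
  fx$uga_pct[2] <- fx$uga_pct[1]
  pca <- feature_pca(fx)
  expect_equal(pca$scores[1, ], pca$scores[2, ], tolerance = 1e-12)

  perm <- sample(nrow(fx))
  pca_p <- feature_pca(fx[perm, ])
  expect_equal(pca_p$scores[fx$genome_id, ], pca$scores[fx$genome_id, ],
               tolerance = 1e-8)
})

test_that("rows without Trp are dropped from PCA with a warning", {
  fx <- data.frame(genome_id = c("a", "b", "c", "d"),
                   motif_present = c(TRUE, FALSE, TRUE, FALSE),
                   rdrp_len_aa = c(1000L, 700L, 950L, 600L),
                   uga_pct = c(10, NA, 30, 5))
  expect_warning(pca <- feature_pca(fx), "dropped")
  expect_identical(rownames(pca$scores), c("a", "c", "d"))
  expect_error(suppressWarnings(
    feature_pca(fx[c(1, 2, 3), ][c(1, 2), ])), "at least 3")
})

test_that("PC1 separates planted classes with zero overlap", {
  ms <- gen_motif_seed(seed = 25)
  prof <- build_profile(ms$alignment)
  prof$threshold <- calibrate_threshold(prof, fpr = 1e-4, n_samples = 400,
                                        seed = 26)
  sim <- gen_genomes(n_large = 6, n_normal = 6, motif = ms$consensus,
                     seed = 27)
  fx <- extract_features_all(sim$genomes, prof)
  pca <- feature_pca(fx)
  pc1 <- pca$scores[, 1]
  large <- pc1[sim$truth$class[match(names(pc1), sim$truth$genome_id)] ==
                 "large"]
  normal <- pc1[setdiff(names(pc1), names(large))]
  expect_true(min(large) > max(normal) || min(normal) > max(large))
})
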
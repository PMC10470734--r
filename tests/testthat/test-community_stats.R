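test_that("community matrix counts assignments per site and group", {
  assignments <- data.frame(
    query_id = c("q1", "q2", "q3"),
    genus = c("Duamitovirus", "Duamitovirus", "Unuamitovirus"),
    host_taxon = c("Ascomycota", "Ascomycota", "plant"))
  meta <- data.frame(seq_id = c("q1", "q2", "q3"),
                     site_id = c("s1", "s1", "s1"))
  m <- build_community_matrix(assignments, meta)
  expect_identical(dim(m), c(1L, 2L))
  expect_identical(as.integer(m["s1", ]), c(2L, 1L))

  expect_error(build_community_matrix(assignments[0, ], meta), "empty")
  meta_bad <- meta[1:2, ]
  expect_error(build_community_matrix(assignments, meta_bad),
               "not resolvable.*q3")
})

test_that("community matrix row sums equal per-site assignment counts", {
  cm <- gen_community(n_sites = 6, n_libraries = 30, seed = 46)
  m <- build_community_matrix(cm$assignments, cm$meta)
  per_site <- table(cm$meta$site_id)
  expect_identical(rowSums(m)[names(per_site)],
                   stats::setNames(as.numeric(per_site), names(per_site)))
})

test_that("Bray-Curtis follows its definition and semimetric properties", {
  expect_equal(bray_curtis(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(bray_curtis(c(2, 0), c(0, 5)), 1)
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)  # 1/5 by hand
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(47)
  for (rep in 1:20) {
    x <- rpois(6, 4); y <- rpois(6, 4)
    if (sum(x) + sum(y) == 0) next
    expect_equal(bray_curtis(x, y), bray_curtis(y, x))
    expect_gte(bray_curtis(x, y), 0)
    expect_lte(bray_curtis(x, y), 1)
    if (all(x == y)) expect_equal(bray_curtis(x, y), 0)
  }
})

test_that("Bray-Curtis matrix agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  set.seed(48)
  m <- matrix(rpois(60, 5) + 1, nrow = 6)
  D <- bray_curtis_matrix(m)
  expect_equal(as.dist(D), vegan::vegdist(m, method = "bray"),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("isotonic regression matches hand and brute-force solutions", {
  expect_equal(isotonic_fit(c(3, 1, 2)), c(2, 2, 2))
  expect_equal(isotonic_fit(c(1, 2, 3)), c(1, 2, 3))
  set.seed(49)
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    y <- round(runif(n, 0, 10), 2)
    w <- sample(1:4, n, replace = TRUE)
    expect_equal(isotonic_fit(y, w), oracle_isotonic(y, w),
                 tolerance = 1e-9)
  }
  # unweighted case cross-checked against stats::isoreg
  y <- runif(20)
  expect_equal(isotonic_fit(y), stats::isoreg(y)$yf, tolerance = 1e-12)
})

test_that("NMDS embeds perfectly embeddable configurations at ~zero stress", {
  set.seed(50)
  pts <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(dist(pts))
  fit <- nmds(D, k = 2, n_starts = 4, seed = 51)
  expect_lte(fit$stress1, 1e-4)
  expect_identical(fit$stress1, min(fit$stress_per_start))
})

test_that("NMDS is deterministic under a fixed seed", {
  cmn <- gen_community(n_sites = 8, n_libraries = 40, seed = 52)
  D <- bray_curtis_matrix(build_community_matrix(cmn$assignments, cmn$meta))
  f1 <- nmds(D, n_starts = 4, seed = 53)
  f2 <- nmds(D, n_starts = 4, seed = 53)
  expect_identical(f1$coords, f2$coords)
  expect_identical(f1$stress1, f2$stress1)
})

test_that("NMDS stress is close to an independent reference implementation", {
  skip_if_not_installed("vegan")
  # crafted non-embeddable 6-point dissimilarity
  set.seed(54)
  D <- matrix(0, 6, 6)
  D[upper.tri(D)] <- runif(15, 0.2, 1)
  D <- D + t(D)
  fit <- nmds(D, k = 2, n_starts = 20, seed = 55)
  ref <- vegan::monoMDS(as.dist(D), k = 2, model = "global")
  expect_lt(abs(fit$stress1 - ref$stress), 0.005)
})

test_that("stress is invariant to rotation, reflection and translation", {
  set.seed(56)
  D <- matrix(0, 7, 7)
  D[upper.tri(D)] <- runif(21, 0.1, 1)
  D <- D + t(D)
  fit <- nmds(D, k = 2, n_starts = 5, seed = 57)
  x <- fit$coords
  theta <- 0.83
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  for (xt in list(x %*% R, -x, sweep(x, 2, c(3, -1), "+"))) {
    expect_equal(nmds_stress(D, xt), fit$stress1, tolerance = 1e-9)
  }
})

test_that("envfit recovers a variable equal to an ordination axis", {
  set.seed(58)
  coords <- matrix(rnorm(40), 20, 2)
  env <- data.frame(ax1 = coords[, 1], noise = rnorm(20))
  ef <- envfit_perm(coords, env, n_perm = 199, seed = 59)
  ax1 <- ef[ef$variable == "ax1", ]
  expect_equal(ax1$r_squared, 1, tolerance = 1e-9)
  expect_equal(ax1$p_perm, 1 / 200)
  expect_gte(min(ef$p_perm), 1 / 200)
  expect_warning(
    envfit_perm(coords, data.frame(flat = rep(1, 20), ok = rnorm(20)),
                n_perm = 49), "zero-variance")
})

test_that("envfit r-squared agrees with vegan::envfit", {
  skip_if_not_installed("vegan")
  set.seed(60)
  coords <- matrix(rnorm(30), 15, 2)
  v <- coords[, 1] * 0.6 + rnorm(15, sd = 0.5)
  ef <- envfit_perm(coords, data.frame(v = v), n_perm = 99, seed = 61)
  ref <- vegan::envfit(coords, data.frame(v = v), permutations = 99)
  expect_equal(ef$r_squared, unname(ref$vectors$r), tolerance = 1e-9)
})

test_that("Pearson test matches hand computation and cor.test", {
  ct <- pearson_test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(ct$r, 0.8)
  expect_equal(ct$t_stat, 0.8 * sqrt(2 / (1 - 0.64)), tolerance = 1e-12)
  expect_identical(ct$df, 2L)

  perfect <- pearson_test(1:5, 1:5)
  expect_equal(perfect$r, 1)
  expect_identical(perfect$t_stat, Inf)
  expect_lte(perfect$p_two_sided, .Machine$double.xmin)

  set.seed(62)
  for (rep in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    got <- pearson_test(x, y)
    ref <- stats::cor.test(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_test(rep(1, 5), 1:5), "zero variance")
})

test_that("a planted environmental gradient is detected by envfit", {
  n_sig <- 0L
  for (s in 1:25) {
    cmn <- gen_community(seed = 700 + s)
    m <- build_community_matrix(cmn$assignments, cmn$meta)
    fit <- nmds(bray_curtis_matrix(m), n_starts = 5, max_iter = 200,
                seed = s)
    env <- factor_frequencies(cmn$library_meta, sites = rownames(m))
    ef <- envfit_perm(fit$coords, env["ecosystem.soil"], n_perm = 199,
                      seed = s)
    n_sig <- n_sig + (ef$p_perm < 0.05)
  }
  expect_gte(n_sig, 21L)
})
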
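# Community-scale analyses: site x (genus x host) count matrices from
# top-hit assignments, NMDS (Kruskal stress-1 on Bray-Curtis), permutation
# environment fitting, and the per-library co-occurrence correlation.

#' Build a site-by-group community matrix from assignments
#'
#' @param assignments data.frame from [assign_all()] (query_id, genus,
#'   host_taxon, ...).
#' @param meta data.frame mapping sequences to sites: columns `seq_id` and
#'   `site_id` (one row per sequence).
#' @param group_by Columns of `assignments` combined (":"-joined) into the
#'   group key (default genus x host_taxon).
#' @return Integer matrix, rows = sorted site ids, columns = sorted group
#'   keys; all-zero site rows are dropped with a warning.
#' @export
build_community_matrix <- function(assignments, meta,
                                   group_by = c("genus", "host_taxon")) {
  if (nrow(assignments) == 0L) stop("no assignments: community is empty")
  site <- meta$site_id[match(assignments$query_id, meta$seq_id)]
  if (anyNA(site)) {
    bad <- assignments$query_id[is.na(site)]
    stop("query id(s) not resolvable to a site: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5))
  }
  key <- do.call(paste, c(assignments[group_by], sep = ":"))
  tab <- table(factor(site, levels = sort(unique(site))),
               factor(key, levels = sort(unique(key))))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  empty <- rowSums(m) == 0L
  if (any(empty)) {
    warning("dropping all-zero site row(s): ",
            paste(rownames(m)[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
  }
  m
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `sum(|x - y|) / sum(x + y)`, in [0, 1] for non-negative input.
#'
#' @param x,y Equal-length non-negative count vectors, not both all-zero.
#' @return Numeric scalar.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both vectors are all-zero: dissimilarity undefined")
  sum(abs(x - y)) / tot
}

#' Bray-Curtis dissimilarity matrix of a community matrix
#'
#' @param m Sites x groups count matrix.
#' @return Symmetric n x n dissimilarity matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  D
}

#' Weighted least-squares isotonic regression (pool-adjacent-violators)
#'
#' Fits the non-decreasing vector minimizing `sum(w * (y - fit)^2)`.
#'
#' @param y Numeric vector in the target order.
#' @param w Positive weights (default unit).
#' @return The fitted non-decreasing vector.
#' @export
isotonic_fit <- function(y, w = rep(1, length(y))) {
  stopifnot(length(y) == length(w), all(w > 0))
  n <- length(y)
  if (n == 0L) return(numeric(0))
  # blocks as (value, weight, size) stacks
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      wnew <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) / wnew
      wt[top - 1L] <- wnew
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], sz[seq_len(top)])
}

# Stress-1 machinery. Pairs are ordered by dissimilarity; Kruskal's primary
# tie treatment lets tied blocks order freely, realized by sorting
# configuration distances ascending within tied blocks before PAVA.
.pair_index <- function(n) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
}

.config_dist <- function(x, pairs) {
  d2 <- rowSums((x[pairs[, 1], , drop = FALSE] -
                 x[pairs[, 2], , drop = FALSE])^2)
  sqrt(pmax(d2, 1e-300))
}

.stress1 <- function(d, dis_order_key) {
  ord <- order(dis_order_key, d)
  dhat <- numeric(length(d))
  dhat[ord] <- isotonic_fit(d[ord])
  s <- sum((d - dhat)^2)
  t <- sum(d^2)
  list(stress = sqrt(s / t), dhat = dhat)
}

#' Stress-1 of a configuration against a dissimilarity matrix
#'
#' @param D Symmetric dissimilarity matrix.
#' @param x n x k configuration.
#' @return Kruskal stress-1 in [0, 1].
#' @export
nmds_stress <- function(D, x) {
  pairs <- .pair_index(nrow(D))
  dis <- D[pairs]
  .stress1(.config_dist(as.matrix(x), pairs), dis)$stress
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Iteratively minimizes stress-1 by gradient descent with step halving,
#' with the monotone fit recomputed (pool-adjacent-violators, primary tie
#' treatment) each iteration. One start is classical metric scaling
#' (`cmdscale`), the rest random Gaussian configurations; the best final
#' solution is returned centered and rotated to its principal axes.
#'
#' @param D Symmetric non-negative dissimilarity matrix with zero diagonal.
#' @param k Target dimension (default 2).
#' @param n_starts Number of starts (default 20).
#' @param max_iter Iterations per start (default 500).
#' @param tol Convergence tolerance on the relative stress change
#'   (default 1e-7).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return `nmds_result`: `coords` (n x k), `stress1`, `n_starts`,
#'   `converged`, `best_start_index`, `seed`, `stress_per_start`.
#' @export
nmds <- function(D, k = 2L, n_starts = 20L, max_iter = 500L, tol = 1e-7,
                 seed = 1L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < k + 1L) stop("need at least k + 1 points")
  if (any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0) || any(D < 0)) {
    stop("D must be symmetric and non-negative with zero diagonal")
  }
  pairs <- .pair_index(n)
  dis <- D[pairs]

  run_start <- function(x0) {
    x <- x0
    d <- .config_dist(x, pairs)
    fit <- .stress1(d, dis)
    stress <- fit$stress
    step <- 0.1 * mean(d)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      if (stress < 1e-12) { converged <- TRUE; break }
      dhat <- fit$dhat
      s_num <- sum((d - dhat)^2)
      t_den <- sum(d^2)
      # gradient of sqrt(S/T) wrt coordinates, monotone fit held fixed
      coef <- ((d - dhat) * t_den - d * s_num) / d
      g <- matrix(0, n, k)
      diffs <- x[pairs[, 1], , drop = FALSE] - x[pairs[, 2], , drop = FALSE]
      contrib <- diffs * coef
      for (a in seq_len(k)) {
        g[, a] <- tapply(c(contrib[, a], -contrib[, a]),
                         c(pairs[, 1], pairs[, 2]), sum)[as.character(seq_len(n))]
      }
      g <- g / (stress * t_den^2)
      gn <- sqrt(sum(g^2))
      if (gn < 1e-14) { converged <- TRUE; break }
      improved <- FALSE
      step <- step * 2
      for (h in seq_len(40L)) {
        x_new <- x - (step / gn) * g
        d_new <- .config_dist(x_new, pairs)
        fit_new <- .stress1(d_new, dis)
        if (fit_new$stress < stress) { improved <- TRUE; break }
        step <- step / 2
      }
      if (!improved) { converged <- TRUE; break }
      rel <- (stress - fit_new$stress) / stress
      x <- x_new; d <- d_new; fit <- fit_new; stress <- fit_new$stress
      if (rel < tol) { converged <- TRUE; break }
    }
    list(x = x, stress = stress, converged = converged)
  }

  results <- .with_seed(seed, {
    starts <- vector("list", n_starts)
    x0 <- suppressWarnings(stats::cmdscale(D, k = k))
    if (ncol(x0) < k) {
      x0 <- cbind(x0, matrix(stats::rnorm(n * (k - ncol(x0)), sd = 1e-4),
                             nrow = n))
    }
    starts[[1]] <- x0
    for (s in seq_len(n_starts)[-1]) {
      starts[[s]] <- matrix(stats::rnorm(n * k), n, k) * mean(dis)
    }
    lapply(starts, run_start)
  })
  stresses <- vapply(results, `[[`, numeric(1), "stress")
  best <- which.min(stresses)
  x <- results[[best]]$x
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  x <- sv$u %*% diag(sv$d, nrow = k)
  for (j in seq_len(k)) {  # deterministic reflection
    m <- which.max(abs(x[, j]))
    if (x[m, j] < 0) x[, j] <- -x[, j]
  }
  dimnames(x) <- list(rownames(D), paste0("NMDS", seq_len(k)))
  structure(list(coords = x, stress1 = stresses[best],
                 n_starts = n_starts, converged = results[[best]]$converged,
                 best_start_index = best, seed = seed,
                 stress_per_start = stresses),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("nmds_result:", nrow(x$coords), "points,", ncol(x$coords),
      "dimensions; stress-1 =", formatC(x$stress1, digits = 4), "\n")
  invisible(x)
}

#' Per-site frequencies of metadata factor categories
#'
#' For each site, the proportion of its libraries falling in each category
#' of each factor -- the per-site environmental variables fitted onto the
#' ordination.
#'
#' @param meta One row per library: site_id plus factor columns.
#' @param factors Factor column names (default ecosystem, sample_type).
#' @param sites Site ids (row order); default sorted unique site ids.
#' @return data.frame, rows = sites, columns `<factor>.<category>`.
#' @export
factor_frequencies <- function(meta,
                               factors = c("ecosystem", "sample_type"),
                               sites = sort(unique(meta$site_id))) {
  out <- data.frame(row.names = sites)
  for (f in factors) {
    tab <- table(factor(meta$site_id, levels = sites), meta[[f]])
    freq <- tab / pmax(rowSums(tab), 1L)
    for (cat in colnames(freq)) {
      out[[paste(f, cat, sep = ".")]] <- as.numeric(freq[, cat])
    }
  }
  out
}

#' Fit environmental variables onto ordination axes by permutation
#'
#' For each variable, the coefficient of determination of its least-squares
#' regression on the k axes; the direction is the unit-normalized vector of
#' regression coefficients; significance is by permuting the variable
#' across sites, with the add-one estimator
#' `p = (1 + #(permuted r2 >= observed)) / (n_perm + 1)`.
#'
#' @param coords n x k ordination coordinates.
#' @param env data.frame of per-site numeric variables (rows align with
#'   `coords` rows).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return data.frame: variable, one direction column per axis, r_squared,
#'   p_perm, n_perm. Zero-variance variables are skipped with a warning.
#' @export
envfit_perm <- function(coords, env, n_perm = 999L, seed = 1L) {
  coords <- as.matrix(coords)
  stopifnot(nrow(env) == nrow(coords))
  Xc <- scale(coords, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  k <- ncol(coords)
  rsq <- function(v) {
    vc <- v - mean(v)
    ss <- sum(vc^2)
    fit <- qr.fitted(qrX, vc)
    sum(fit^2) / ss
  }
  rows <- list()
  perms <- .with_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample.int(nrow(coords)))
  })
  for (nm in names(env)) {
    v <- as.numeric(env[[nm]])
    if (stats::sd(v) == 0) {
      warning("zero-variance variable skipped: ", nm)
      next
    }
    obs <- rsq(v)
    beta <- qr.coef(qrX, v - mean(v))
    beta[is.na(beta)] <- 0
    dir <- beta / sqrt(sum(beta^2))
    null <- vapply(perms, function(p) rsq(v[p]), numeric(1))
    p <- (1 + sum(null >= obs)) / (n_perm + 1)
    row <- data.frame(variable = nm, t(dir), r_squared = obs,
                      p_perm = p, n_perm = n_perm,
                      stringsAsFactors = FALSE)
    names(row)[2:(1 + k)] <- paste0("NMDS", seq_len(k))
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) stop("no variable with nonzero variance")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation with Student's t test
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to the t distribution with
#' n - 2 degrees of freedom (two-sided).
#'
#' @param x,y Numeric vectors, length >= 3, each with nonzero variance.
#' @return List: r, t_stat, df, p_two_sided, n.
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  if (abs(r) >= 1 - 1e-15) {
    t <- sign(r) * Inf
    p <- .Machine$double.xmin  # minimal representable two-sided p
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(r = r, t_stat = t, df = df, p_two_sided = p, n = n)
}
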
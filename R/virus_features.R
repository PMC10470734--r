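# The three classification factors -- N-terminal motif presence, RdRp
# length, and %UGA-for-Trp -- plus the large-duamitovirus rule
# (RdRp >= 900 aa AND motif present) and the three-factor PCA.

#' Tryptophan codon usage of an ORF
#'
#' %UGA is computed on the Trp denominator only: among codons translated as
#' Trp (UGA under table 4, plus UGG), the percentage encoded by UGA. With no
#' Trp residues the percentage is undefined (`NA`).
#'
#' @param codons Character vector of the ORF's RNA codons (protein part,
#'   stop excluded), e.g. the `codons` list-column of [find_orfs()].
#' @param protein Matching amino-acid string (consistency-checked).
#' @return List with `uga_pct` (0-100 or `NA`) and `n_trp`.
#' @export
trp_codon_usage <- function(codons, protein = NULL) {
  if (!is.null(protein)) {
    if (length(codons) != nchar(protein)) {
      stop("codon/protein length mismatch: ", length(codons), " codons vs ",
           nchar(protein), " residues")
    }
    aa <- strsplit(protein, "", fixed = TRUE)[[1]]
    is_w <- codons %in% c("UGA", "UGG")
    if (!all(aa[is_w] == "W") || !all(codons[aa == "W"] %in% c("UGA", "UGG"))) {
      stop("codon/protein inconsistency: Trp residues and UGA/UGG codons disagree")
    }
  }
  n_uga <- sum(codons == "UGA")
  n_trp <- n_uga + sum(codons == "UGG")
  list(uga_pct = if (n_trp == 0L) NA_real_ else 100 * n_uga / n_trp,
       n_trp = as.integer(n_trp))
}

#' Extract the three classification factors for one genome
#'
#' Chains the dual-code ORF caller ([find_orfs_both()], [select_rdrp()]),
#' the motif scan of the selected RdRp, and [trp_codon_usage()].
#'
#' @param seq RNA genome string.
#' @param genome_id Id carried into the output row.
#' @param profile Calibrated [build_profile()] result.
#' @param min_len_aa Minimum ORF length for enumeration (default 100).
#' @param n_terminal_window Passed to [scan_protein()].
#' @return One-row data.frame: genome_id, motif_present, rdrp_len_aa,
#'   uga_pct, n_trp, motif_pos, motif_score, rdrp_code, rdrp_frame.
#' @export
extract_features <- function(seq, genome_id = "genome", profile,
                             min_len_aa = 100L, n_terminal_window = 100L) {
  orfs <- find_orfs_both(seq, genome_id, min_len_aa)
  rdrp <- select_rdrp(orfs)
  hit <- scan_protein(profile, rdrp$protein, n_terminal_window)
  usage <- trp_codon_usage(rdrp$codons[[1]], rdrp$protein)
  data.frame(genome_id = genome_id,
             motif_present = isTRUE(hit$present),
             rdrp_len_aa = rdrp$length_aa,
             uga_pct = usage$uga_pct,
             n_trp = usage$n_trp,
             motif_pos = hit$position_aa,
             motif_score = hit$score,
             rdrp_code = rdrp$code,
             rdrp_frame = rdrp$frame,
             stringsAsFactors = FALSE)
}

#' Extract features for a collection of genomes
#'
#' @param seqs Named character vector of RNA genomes.
#' @inheritParams extract_features
#' @return data.frame with one row per genome (see [extract_features()]).
#' @export
extract_features_all <- function(seqs, profile, min_len_aa = 100L,
                                 n_terminal_window = 100L) {
  rows <- lapply(seq_along(seqs), function(i) {
    extract_features(seqs[[i]], names(seqs)[i], profile,
                     min_len_aa, n_terminal_window)
  })
  do.call(rbind, rows)
}

#' Apply the large-duamitovirus classification rule
#'
#' A genome is a large duamitovirus iff its RdRp is 900 aa or longer
#' (inclusive boundary) AND carries the N-terminal motif; all others are
#' OTHER, with the failed criteria listed.
#'
#' @param features Feature table from [extract_features_all()].
#' @param min_len_aa Length threshold (default 900 aa).
#' @return `features` with columns `label`
#'   (`"LARGE_DUAMITOVIRUS"`/`"OTHER"`) and `reasons` appended.
#' @export
classify <- function(features, min_len_aa = 900L) {
  stopifnot(all(c("motif_present", "rdrp_len_aa") %in% names(features)))
  reasons <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    r <- character(0)
    if (!isTRUE(features$motif_present[i])) r <- c(r, "no N-terminal motif")
    if (features$rdrp_len_aa[i] < min_len_aa) {
      r <- c(r, sprintf("RdRp shorter than %d aa", min_len_aa))
    }
    reasons[i] <- paste(r, collapse = "; ")
  }
  features$label <- ifelse(reasons == "", "LARGE_DUAMITOVIRUS", "OTHER")
  features$reasons <- reasons
  features
}

#' Three-factor principal component analysis
#'
#' Motif presence is encoded 0/1; the three columns (motif, RdRp length,
#' %UGA) are centered and scaled to unit variance, and scores are taken from
#' the singular value decomposition of the standardized matrix. Rows with
#' undefined %UGA (no Trp) are dropped with a warning. Sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param features Feature table with motif_present, rdrp_len_aa, uga_pct.
#' @param k Number of components (default 2).
#' @return List of class `feature_pca`: `scores` (n x k, rownames =
#'   genome ids), `loadings` (3 x k), `explained_variance` (k eigenvalues of
#'   the correlation matrix), `center`, `scale`, `kept_ids`.
#' @export
feature_pca <- function(features, k = 2L) {
  keep <- !is.na(features$uga_pct)
  if (!all(keep)) {
    warning(sum(!keep), " row(s) with undefined %UGA (no Trp) dropped")
  }
  f <- features[keep, , drop = FALSE]
  if (nrow(f) < 3L) stop("need at least 3 rows with defined %UGA for PCA")
  X <- cbind(motif = as.numeric(f$motif_present),
             length = as.numeric(f$rdrp_len_aa),
             uga_pct = as.numeric(f$uga_pct))
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) stop("all three factors are constant")
  zero_var <- sds == 0
  if (any(zero_var)) {
    warning("zero-variance factor(s): ",
            paste(colnames(X)[zero_var], collapse = ", "),
            " contribute all-zero standardized scores")
    sds[zero_var] <- 1  # column becomes identically 0 after centering
  }
  Z <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  sv <- svd(Z)
  k <- min(k, ncol(Z))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|.| loading of each component positive
  for (j in seq_len(k)) {
    m <- which.max(abs(loadings[, j]))
    if (loadings[m, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- f$genome_id
  rownames(loadings) <- colnames(X)
  ev <- sv$d^2 / (nrow(Z) - 1)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(k)],
                 center = ctr, scale = sds, kept_ids = f$genome_id),
            class = "feature_pca")
}

#' @export
print.feature_pca <- function(x, ...) {
  cat("feature_pca:", nrow(x$scores), "rows,", ncol(x$scores),
      "components; explained variance",
      paste(formatC(x$explained_variance, digits = 3, format = "f"),
            collapse = ", "), "\n")
  invisible(x)
}
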
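# Position-specific log-odds profile of the conserved N-terminal motif
# (a 53-58 aa block at the RdRp amino terminus), built from a seed alignment
# and scanned ungapped over proteins and all six genome reading frames.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Pooled amino-acid background frequencies
#'
#' @param seqs Character vector of protein sequences ('X' ignored).
#' @return Named 20-vector of frequencies summing to 1.
#' @export
aa_background <- function(seqs) {
  ch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  counts <- table(factor(ch, levels = AA20))
  tot <- sum(counts)
  if (tot == 0L) stop("no standard residues in input")
  stats::setNames(as.numeric(counts) / tot, AA20)
}

#' Build a log-odds motif profile from a seed alignment
#'
#' Columns with gap fraction >= 0.5 are dropped (with a warning). Column
#' frequencies use background-weighted pseudocounts,
#' `f_a = (count_a + pc * bg_a) / (N_eff + pc)`, where `N_eff` is the number
#' of non-gap residues in the column; scores are `ln(f_a / bg_a)`.
#'
#' @param seed Named character vector of equal-length aligned protein rows
#'   (see [read_alignment()]).
#' @param pseudocount Positive pseudocount mass (default 1).
#' @param background Named 20-vector of amino-acid frequencies; `NULL` for
#'   uniform 1/20.
#' @return A `motif_profile`: list with `width`, `log_odds` (20 x width),
#'   `background`, `pseudocount`, `threshold` (NA until calibrated).
#' @export
build_profile <- function(seed, pseudocount = 1, background = NULL) {
  stopifnot(length(seed) >= 1L, pseudocount > 0)
  if (length(unique(nchar(seed))) != 1L) stop("ragged alignment")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA20)
  }
  background <- background[AA20]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-6) {
    stop("background must be a named 20-vector of frequencies summing to 1")
  }
  mat <- do.call(rbind, strsplit(seed, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  drop <- gap_frac >= 0.5
  if (any(drop)) {
    warning(sum(drop), " column(s) with gap fraction >= 0.5 dropped")
    mat <- mat[, !drop, drop = FALSE]
  }
  w <- ncol(mat)
  if (w < 5L) stop("profile width < 5 after gap-column removal")
  lo <- matrix(0, nrow = 20, ncol = w,
               dimnames = list(AA20, paste0("p", seq_len(w))))
  for (j in seq_len(w)) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    counts <- table(factor(col, levels = AA20))
    n_eff <- length(col)
    f <- (as.numeric(counts) + pseudocount * background) /
      (n_eff + pseudocount)
    stopifnot(abs(sum(f) - 1) < 1e-9)
    lo[, j] <- log(f / background)
  }
  structure(list(width = w, log_odds = lo, background = background,
                 pseudocount = pseudocount, threshold = NA_real_),
            class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("motif_profile: width", x$width,
      "| pseudocount", x$pseudocount,
      "| threshold", if (is.na(x$threshold)) "uncalibrated"
      else formatC(x$threshold, digits = 4, format = "f"), "\n")
  invisible(x)
}

# All window scores of a protein against the profile; 'X' scores 0 in every
# column (the expectation of a log-odds column under the background).
score_windows <- function(profile, protein) {
  w <- profile$width
  n <- nchar(protein)
  if (n < w) return(numeric(0))
  idx <- match(strsplit(protein, "", fixed = TRUE)[[1]], AA20,
               nomatch = 21L)
  lo <- rbind(profile$log_odds, 0)
  nwin <- n - w + 1L
  pos <- outer(seq_len(w) - 1L, seq_len(nwin), "+")  # w x nwin residue index
  vals <- lo[cbind(as.vector(idx[pos]), rep.int(seq_len(w), nwin))]
  colSums(matrix(vals, nrow = w))
}

#' Scan a protein for the motif
#'
#' Returns the maximum-scoring ungapped window. The motif counts as present
#' only when the score reaches the calibrated threshold *and* the window
#' starts within the N-terminal window of the protein.
#'
#' @param profile A [build_profile()] result with `threshold` set.
#' @param protein Protein string.
#' @param n_terminal_window Maximum 0-based start offset for an N-terminal
#'   hit (default 100 aa).
#' @return List with `position_aa` (0-based best-window start), `score`, and
#'   `present`. Proteins shorter than the profile width get score `-Inf` and
#'   `present = FALSE`.
#' @export
scan_protein <- function(profile, protein, n_terminal_window = 100L) {
  stopifnot(inherits(profile, "motif_profile"))
  sc <- score_windows(profile, protein)
  if (length(sc) == 0L) {
    return(list(position_aa = NA_integer_, score = -Inf, present = FALSE))
  }
  best <- which.max(sc)
  pos <- best - 1L
  present <- if (is.na(profile$threshold)) NA else
    (sc[best] >= profile$threshold) && (pos <= n_terminal_window)
  list(position_aa = pos, score = unname(sc[best]), present = present)
}

#' Scan all six reading frames of a genome for the motif
#'
#' Each frame is translated in full; stop codons split the translation into
#' segments and every segment of at least the profile width is scanned. All
#' windows scoring at or above the calibrated threshold are reported.
#'
#' @param profile Calibrated [build_profile()] result.
#' @param seq RNA genome string.
#' @param code A table from [genetic_code()] (table 4 by default, so UGA
#'   does not truncate segments).
#' @return data.frame with columns frame, position_aa (0-based offset of the
#'   window start in the frame translation), score, sorted by score
#'   descending.
#' @export
scan_genome_frames <- function(profile, seq, code = genetic_code(4L)) {
  stopifnot(inherits(profile, "motif_profile"))
  if (is.na(profile$threshold)) stop("profile threshold not calibrated")
  if (nchar(seq) < 3L * profile$width) stop("genome shorter than 3 x width")
  rc <- reverse_complement(seq)
  hits <- list()
  for (frame in 0:5) {
    s <- if (frame < 3L) seq else rc
    codons <- .codons_of(s, frame %% 3L)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    breaks <- c(0L, which(aa == "*"), length(aa) + 1L)
    for (b in seq_len(length(breaks) - 1L)) {
      lo <- breaks[b] + 1L
      hi <- breaks[b + 1L] - 1L
      if (hi - lo + 1L < profile$width) next
      seg <- paste(aa[lo:hi], collapse = "")
      sc <- score_windows(profile, seg)
      keep <- which(sc >= profile$threshold)
      for (k in keep) {
        hits[[length(hits) + 1L]] <- data.frame(
          frame = frame, position_aa = lo - 1L + k - 1L,
          score = unname(sc[k]))
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(frame = integer(0), position_aa = integer(0),
                      score = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate the motif score threshold at a target false-positive rate
#'
#' Draws random background proteins, records each protein's maximum window
#' score, and returns the (1 - fpr) quantile of that null distribution: the
#' per-protein probability that a random protein reaches the threshold is
#' then approximately `fpr`.
#'
#' @param profile A [build_profile()] result.
#' @param fpr Target per-protein false-positive rate in (0, 1).
#' @param n_samples Number of null proteins (default 1000).
#' @param len Null protein length (default 300 aa).
#' @param background Named 20-vector; defaults to the profile's background.
#' @param seed Integer seed; equal seeds give identical thresholds.
#' @return The threshold (numeric scalar). Assign it to
#'   `profile$threshold` to activate presence calls.
#' @export
calibrate_threshold <- function(profile, fpr = 1e-4, n_samples = 1000L,
                                len = 300L, background = NULL, seed = 1L) {
  stopifnot(inherits(profile, "motif_profile"))
  if (!(fpr > 0 && fpr < 1)) stop("fpr must be in (0, 1)")
  if (is.null(background)) background <- profile$background
  null_max <- .with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      p <- paste(sample(AA20, len, replace = TRUE, prob = background),
                 collapse = "")
      max(score_windows(profile, p))
    }, numeric(1))
  })
  unname(stats::quantile(null_max, probs = 1 - fpr, type = 7))
}
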
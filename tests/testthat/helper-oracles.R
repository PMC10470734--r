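# Independent brute-force oracles used to verify the package's
# implementations. Deliberately naive: character-by-character loops,
# exhaustive enumeration, no shared code with the implementation paths.

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")

rand_protein_str <- function(n) {
  paste(sample(mitoscreen:::AA20, n, replace = TRUE), collapse = "")
}

# codon-by-codon translation oracle
oracle_translate <- function(seq, code, offset = 0L) {
  out <- character(0)
  i <- offset + 1L
  while (i + 2L <= nchar(seq)) {
    aa <- unname(code[[substr(seq, i, i + 2L)]])
    if (aa == "*") break
    out <- c(out, aa)
    i <- i + 3L
  }
  paste(out, collapse = "")
}

# every AUG scanned to its next in-frame stop; nested ORFs sharing a stop
# collapsed to the earliest AUG (the first-AUG-per-segment policy)
oracle_orfs <- function(seq, code, min_len_aa) {
  L <- nchar(seq)
  rc <- mitoscreen::reverse_complement(seq)
  rows <- list()
  for (frame in 0:5) {
    s <- if (frame < 3) seq else rc
    off <- frame %% 3
    codon_at <- function(i) substr(s, off + 3 * (i - 1) + 1, off + 3 * i)
    n_codons <- (nchar(s) - off) %/% 3
    if (n_codons == 0) next
    calls <- list()
    for (i in seq_len(n_codons)) {
      if (codon_at(i) != "AUG") next
      j <- i
      protein <- character(0)
      stop_idx <- NA
      while (j <= n_codons) {
        aa <- unname(code[[codon_at(j)]])
        if (aa == "*") { stop_idx <- j; break }
        protein <- c(protein, aa)
        j <- j + 1
      }
      calls[[length(calls) + 1]] <- list(start = i, stop = stop_idx,
                                         protein = paste(protein, collapse = ""))
    }
    # earliest AUG per closing barrier
    keys <- vapply(calls, function(cl) {
      if (is.na(cl$stop)) "end" else as.character(cl$stop)
    }, character(1))
    for (k in unique(keys)) {
      grp <- calls[keys == k]
      starts <- vapply(grp, function(cl) cl$start, numeric(1))
      cl <- grp[[which.min(starts)]]
      len <- nchar(cl$protein)
      if (len < min_len_aa) next
      a <- off + 3 * (cl$start - 1)
      b <- if (is.na(cl$stop)) a + 3 * len else off + 3 * cl$stop
      if (frame >= 3) { tmp <- a; a <- L - b; b <- L - tmp }
      rows[[length(rows) + 1]] <- data.frame(
        frame = as.integer(frame), start_nt = as.integer(a),
        end_nt = as.integer(b), length_aa = as.integer(len),
        partial_3prime = is.na(cl$stop),
        protein = cl$protein, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(frame = integer(0), start_nt = integer(0),
                      end_nt = integer(0), length_aa = integer(0),
                      partial_3prime = logical(0), protein = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$frame, out$start_nt), ]
  rownames(out) <- NULL
  out
}

# exhaustive window-scan oracle: per-character lookups, double loop
oracle_best_window <- function(profile, protein) {
  w <- profile$width
  n <- nchar(protein)
  if (n < w) return(list(position_aa = NA, score = -Inf))
  best <- -Inf; best_pos <- NA
  for (start in 1:(n - w + 1)) {
    sc <- 0
    for (j in 1:w) {
      ch <- substr(protein, start + j - 1, start + j - 1)
      if (ch != "X") sc <- sc + profile$log_odds[ch, j]
    }
    if (sc > best) { best <- sc; best_pos <- start - 1 }
  }
  list(position_aa = best_pos, score = best)
}

# exhaustive local alignment oracle: every local alignment is a monotone
# matching of residue pairs; between consecutive matched columns the
# skipped residues of each sequence form one gap run charged
# open + length * extend. Enumerates all matchings of all sizes
# (independent of the Gotoh recurrences).
oracle_sw <- function(a, b, subst, gap_open, gap_extend) {
  ach <- strsplit(a, "")[[1]]; bch <- strsplit(b, "")[[1]]
  n <- length(ach); m <- length(bch)
  best <- 0
  for (k in seq_len(min(n, m))) {
    ia <- utils::combn(n, k, simplify = FALSE)
    jb <- utils::combn(m, k, simplify = FALSE)
    for (ii in ia) for (jj in jb) {
      sc <- sum(subst[cbind(ach[ii], bch[jj])])
      if (k > 1) {
        for (t in 1:(k - 1)) {
          da <- ii[t + 1] - ii[t] - 1
          db <- jj[t + 1] - jj[t] - 1
          if (da > 0) sc <- sc - gap_open - gap_extend * da
          if (db > 0) sc <- sc - gap_open - gap_extend * db
        }
      }
      best <- max(best, sc)
    }
  }
  best
}

# exact monotone least-squares oracle: the optimum is piecewise constant on
# consecutive blocks at block means; enumerate all 2^(n-1) block partitions
oracle_isotonic <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  best <- NULL; best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    for (bi in seq_len(length(bounds) - 1)) {
      idx <- (bounds[bi] + 1):bounds[bi + 1]
      fit[idx] <- sum(w[idx] * y[idx]) / sum(w[idx])
    }
    if (is.unsorted(fit)) next
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
  }
  best
}

make_profile_for_tests <- function(seed = 99, width = 20, n_seqs = 6) {
  ms <- mitoscreen::gen_motif_seed(width = width, n_seqs = n_seqs,
                                   seed = seed)
  list(profile = mitoscreen::build_profile(ms$alignment),
       consensus = ms$consensus, alignment = ms$alignment)
}
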
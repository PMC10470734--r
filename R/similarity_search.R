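# Exact-identity dedupe and top-hit label transfer against a labelled
# reference protein set, using Smith-Waterman local alignment with affine
# gap penalties (the desk-scale equivalent of a Blastp search).

#' Collapse identical sequences (100% identity clustering)
#'
#' Keeps the first occurrence of each distinct full-length sequence string,
#' preserving input order. No containment clustering: two sequences cluster
#' only if they are exactly equal.
#'
#' @param seqs Named character vector of protein sequences.
#' @return List with `seqs` (kept records) and `mapping` (data.frame
#'   kept_id / duplicate_id, one row per removed duplicate).
#' @export
dedupe_exact <- function(seqs) {
  stopifnot(is.character(seqs))
  first <- !duplicated(seqs)
  kept <- seqs[first]
  rep_id <- names(kept)[match(seqs, kept)]
  dup_rows <- which(!first)
  mapping <- data.frame(kept_id = rep_id[dup_rows],
                        duplicate_id = names(seqs)[dup_rows],
                        stringsAsFactors = FALSE)
  list(seqs = kept, mapping = mapping)
}

.get_subst_matrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

.encode_protein <- function(seq, residues) {
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], residues)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("residue '", substr(seq, bad, bad), "' at position ", bad,
         " not in substitution matrix")
  }
  idx
}

#' Smith-Waterman local alignment score
#'
#' Maximal local alignment score under affine gap penalties: a gap of
#' length L costs `gap_open + L * gap_extend` (the Blastp convention, so the
#' defaults 11/1 mirror Blastp defaults with BLOSUM62). Symmetric in its
#' arguments; the empty local alignment scores 0, so scores are never
#' negative.
#'
#' @param a,b Protein strings.
#' @param matrix Substitution matrix name from Biostrings data (default
#'   `"BLOSUM62"`) or a numeric matrix with residue dimnames.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return The alignment score (numeric scalar).
#' @examples
#' sw_align("ACD", "ACD")  # 19 = 4 + 9 + 6 on the BLOSUM62 diagonal
#' @export
sw_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                     gap_extend = 1) {
  stopifnot(gap_open > 0, gap_extend > 0)
  m <- .get_subst_matrix(matrix)
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  res <- rownames(m)
  .sw_score_cpp(.encode_protein(a, res), .encode_protein(b, res),
                m, gap_open, gap_extend)
}

# ids of references sharing at least one 4-mer with the query
.kmer_candidates <- function(query, refs, k = 4L) {
  if (nchar(query) < k) return(names(refs))
  qk <- unique(substring(query, seq_len(nchar(query) - k + 1L),
                         seq_len(nchar(query) - k + 1L) + k - 1L))
  hit <- vapply(refs, function(r) {
    any(vapply(qk, function(km) grepl(km, r, fixed = TRUE), logical(1)))
  }, logical(1))
  names(refs)[hit]
}

#' Assign a query to its top-hit reference
#'
#' Scores the query against every reference with [sw_align()] and transfers
#' the genus and host-taxon labels of the highest-scoring reference; ties
#' are broken by reference order. Below `min_score` the labels become
#' `"unknown"`.
#'
#' @param query Protein string.
#' @param refs Named character vector of reference proteins.
#' @param labels data.frame with columns ref_id, genus, host_taxon
#'   (`NULL` for unlabelled references).
#' @param min_score Scores below this yield `"unknown"` labels.
#' @param query_id Id carried into the output.
#' @param prefilter If `TRUE`, skip references sharing no 4-mer with the
#'   query (never skips the top hit when any 4-mer is shared).
#' @param ... Passed to [sw_align()].
#' @return One-row data.frame: query_id, ref_id, score, genus, host_taxon.
#' @export
top_hit <- function(query, refs, labels = NULL, min_score = 0,
                    query_id = "query", prefilter = FALSE, ...) {
  stopifnot(length(refs) >= 1L, !is.null(names(refs)))
  cand <- if (prefilter) .kmer_candidates(query, refs) else names(refs)
  if (length(cand) == 0L) cand <- names(refs)[1]  # degenerate: keep one
  scores <- vapply(refs[cand], function(r) sw_align(query, r, ...),
                   numeric(1))
  best <- cand[which.max(scores)]  # which.max keeps the earliest tie
  sc <- unname(max(scores))
  genus <- host <- "unknown"
  if (sc >= min_score && !is.null(labels)) {
    row <- labels[labels$ref_id == best, , drop = FALSE]
    if (nrow(row) == 1L) {
      genus <- row$genus
      host <- row$host_taxon
    }
  }
  data.frame(query_id = query_id, ref_id = best, score = sc,
             genus = genus, host_taxon = host, stringsAsFactors = FALSE)
}

#' Assign every query to its top-hit reference
#'
#' @param queries Named character vector of query proteins.
#' @inheritParams top_hit
#' @return data.frame with one [top_hit()] row per query.
#' @export
assign_all <- function(queries, refs, labels = NULL, min_score = 0,
                       prefilter = FALSE, ...) {
  rows <- lapply(seq_along(queries), function(i) {
    top_hit(queries[[i]], refs, labels, min_score,
            query_id = names(queries)[i], prefilter = prefilter, ...)
  })
  do.call(rbind, rows)
}

#' Calibrate the minimum acceptance score from shuffled-query nulls
#'
#' Residue-shuffled queries preserve composition and length but destroy
#' homology; the returned quantile of their best-against-references scores
#' is the score below which an assignment is reported as `"unknown"`.
#'
#' @param queries Named character vector of query proteins to shuffle.
#' @param refs Named character vector of reference proteins.
#' @param n_samples Number of shuffled queries to score (default 50).
#' @param quantile Null quantile (default 0.999).
#' @param seed Integer seed.
#' @param ... Passed to [sw_align()].
#' @return The score threshold (numeric scalar).
#' @export
calibrate_min_score <- function(queries, refs, n_samples = 50L,
                                quantile = 0.999, seed = 1L, ...) {
  null_best <- .with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      q <- queries[[sample.int(length(queries), 1L)]]
      q <- paste(sample(strsplit(q, "", fixed = TRUE)[[1]]), collapse = "")
      max(vapply(refs, function(r) sw_align(q, r, ...), numeric(1)))
    }, numeric(1))
  })
  unname(stats::quantile(null_best, probs = quantile, type = 7))
}
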
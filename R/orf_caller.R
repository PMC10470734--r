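# ORF calling under dual genetic codes. Mitoviruses replicate in
# mitochondria, where the mold-mitochondrial code (NCBI table 4) reads UGA
# as Trp instead of stop; both code tables are always evaluated and the
# candidate RdRp is selected across them.

.code_cache <- new.env(parent = emptyenv())

#' Genetic code table as an RNA codon map
#'
#' Returns the full 64-codon map for NCBI translation table 1 (standard) or
#' 4 (mold/protozoan mitochondrial, UGA = Trp), keyed by RNA codons. Stops
#' are encoded as `"*"`.
#'
#' @param table_id 1 or 4.
#' @return Named character vector of length 64 with attribute `table_id`.
#' @examples
#' genetic_code(4)[["UGA"]]  # "W"
#' genetic_code(1)[["UGA"]]  # "*"
#' @export
genetic_code <- function(table_id = 4L) {
  table_id <- as.integer(table_id)
  if (!table_id %in% c(1L, 4L)) stop("supported genetic codes: 1, 4")
  key <- as.character(table_id)
  if (is.null(.code_cache[[key]])) {
    code <- Biostrings::GENETIC_CODE
    names(code) <- chartr("T", "U", names(code))
    if (table_id == 4L) code[["UGA"]] <- "W"
    attr(code, "table_id") <- table_id
    .code_cache[[key]] <- code
  }
  .code_cache[[key]]
}

.codons_of <- function(seq, offset) {
  n <- nchar(seq)
  if (n < offset + 3L) return(character(0))
  starts <- seq.int(offset + 1L, n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

#' Translate an RNA sequence under a stated genetic code
#'
#' Translates consecutive codons from `offset`, stopping at (and excluding)
#' the first stop codon; a trailing partial codon is ignored.
#'
#' @param seq RNA string over A/C/G/U.
#' @param code A code table from [genetic_code()].
#' @param offset Frame offset 0, 1 or 2.
#' @return The amino-acid string.
#' @examples
#' translate_rna("AUGUGAUGGUAA", genetic_code(4))  # "MWW"
#' translate_rna("AUGUGAUGGUAA", genetic_code(1))  # "M"
#' @export
translate_rna <- function(seq, code = genetic_code(4L), offset = 0L) {
  stopifnot(offset %in% 0:2)
  bad <- regexpr("[^ACGU]", seq)
  if (bad > 0L) {
    stop("non-ACGU character at position ", bad, " in RNA sequence")
  }
  if (nchar(seq) < offset + 3L) stop("sequence shorter than one codon at offset")
  codons <- .codons_of(seq, offset)
  aa <- unname(code[codons])
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0L) aa <- aa[seq_len(stop_at[1] - 1L)]
  paste(aa, collapse = "")
}

# ORFs of one frame of an already-oriented sequence; returns a list of
# integer triples (start codon index, end codon index incl. stop or NA,
# partial flag) plus the aa/codon vectors for downstream slicing.
.frame_orfs <- function(codons, aa, min_len_aa) {
  n <- length(codons)
  if (n == 0L) return(list())
  # barriers: stop codons and ambiguous (NA) codons; NA barriers poison the
  # ORF they would close (it overlaps masked ambiguity)
  is_stop <- !is.na(aa) & aa == "*"
  is_na <- is.na(aa)
  barrier <- which(is_stop | is_na)
  seg_start <- c(1L, barrier + 1L)
  seg_end <- c(barrier - 1L, n)  # inclusive codon index of last pre-barrier
  out <- list()
  for (s in seq_along(seg_start)) {
    lo <- seg_start[s]; hi <- seg_end[s]
    if (lo > hi) next
    idx <- lo:hi
    aug <- idx[which(codons[idx] == "AUG")[1]]
    if (is.na(aug)) next
    closing <- if (s <= length(barrier)) barrier[s] else NA_integer_
    if (!is.na(closing) && is_na[closing]) next  # runs into masked ambiguity
    len <- hi - aug + 1L
    if (len < min_len_aa) next
    out[[length(out) + 1L]] <- list(start = aug, stop = closing, len = len)
  }
  out
}

#' Enumerate ORFs in all six reading frames
#'
#' In each frame, an ORF opens at the first AUG following the frame start or
#' the previous stop codon and closes at the next in-frame stop or the
#' sequence end (then flagged 3'-partial). Frames 0-2 are forward offsets,
#' 3-5 offsets on the reverse complement. Coordinates are 0-based half-open
#' on the forward strand of the input; the closing stop codon is included in
#' `end_nt - start_nt` but not in the protein.
#'
#' @param seq RNA genome string (A/C/G/U, N allowed if masked on read).
#' @param genome_id Id carried into the output.
#' @param code A table from [genetic_code()].
#' @param min_len_aa Minimum protein length to report (default 100).
#' @return data.frame with columns genome_id, frame, start_nt, end_nt, code,
#'   length_aa, partial_3prime, protein and a list-column codons, sorted by
#'   (frame, start_nt).
#' @export
find_orfs <- function(seq, genome_id = "genome", code = genetic_code(4L),
                      min_len_aa = 100L) {
  stopifnot(min_len_aa >= 1L)
  bad <- regexpr("[^ACGUN]", seq)
  if (bad > 0L) stop("non-ACGUN character at position ", bad)
  L <- nchar(seq)
  rc <- reverse_complement(seq)
  rows <- list()
  for (frame in 0:5) {
    fwd <- frame < 3L
    off <- frame %% 3L
    s <- if (fwd) seq else rc
    codons <- .codons_of(s, off)
    aa <- unname(code[codons])  # NA for codons containing N
    for (orf in .frame_orfs(codons, aa, min_len_aa)) {
      i1 <- orf$start
      i2 <- if (is.na(orf$stop)) orf$start + orf$len - 1L else orf$stop
      # coordinates on the oriented sequence, then mapped to forward strand
      a <- off + 3L * (i1 - 1L)
      b <- off + 3L * i2
      if (!fwd) { tmp <- a; a <- L - b; b <- L - tmp }
      prot_idx <- i1:(i1 + orf$len - 1L)
      rows[[length(rows) + 1L]] <- list(
        genome_id = genome_id, frame = frame, start_nt = a, end_nt = b,
        code = attr(code, "table_id"), length_aa = orf$len,
        partial_3prime = is.na(orf$stop),
        protein = paste(aa[prot_idx], collapse = ""),
        codons = list(codons[prot_idx])
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(genome_id = character(0), frame = integer(0),
                      start_nt = integer(0), end_nt = integer(0),
                      code = integer(0), length_aa = integer(0),
                      partial_3prime = logical(0), protein = character(0),
                      codons = I(list())))
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(genome_id = r$genome_id, frame = r$frame, start_nt = r$start_nt,
               end_nt = r$end_nt, code = r$code, length_aa = r$length_aa,
               partial_3prime = r$partial_3prime, protein = r$protein,
               codons = I(r$codons), stringsAsFactors = FALSE)
  }))
  df <- df[order(df$frame, df$start_nt), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Enumerate ORFs under both genetic codes
#'
#' Neither code can be assumed a priori: %UGA-for-Trp ranges from 0 to 75%
#' across mitoviruses, so ORFs are enumerated under tables 1 and 4 and the
#' RdRp selected across both.
#'
#' @inheritParams find_orfs
#' @return Row-bound ORF table for code tables 1 and 4.
#' @export
find_orfs_both <- function(seq, genome_id = "genome", min_len_aa = 100L) {
  rbind(find_orfs(seq, genome_id, genetic_code(1L), min_len_aa),
        find_orfs(seq, genome_id, genetic_code(4L), min_len_aa))
}

#' Select the candidate RdRp ORF
#'
#' The longest ORF by amino-acid length; ties prefer code table 4 over 1,
#' then the lower frame, then the lower start coordinate.
#'
#' @param orfs ORF table from [find_orfs()] / [find_orfs_both()].
#' @return The selected one-row ORF table.
#' @export
select_rdrp <- function(orfs) {
  if (is.null(orfs) || nrow(orfs) == 0L) {
    id <- if (!is.null(orfs) && "genome_id" %in% names(orfs) &&
              nrow(orfs) > 0L) orfs$genome_id[1] else "<unknown>"
    stop("no candidate RdRp ORF for genome ", id)
  }
  o <- orfs[order(-orfs$length_aa, -orfs$code, orfs$frame, orfs$start_nt), ,
            drop = FALSE]
  o[1, , drop = FALSE]
}
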
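#' @useDynLib mitoscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal alphabet is RNA: mitovirus genomes are +ssRNA, so DNA input is
# converted on read (T -> U) and all coordinates are 0-based half-open on the
# forward strand of the input sequence.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a FASTA file of nucleotide genomes or proteins
#'
#' Sequences are upper-cased; for nucleotide input, `T` is mapped to `U` so
#' that all downstream code works on the RNA alphabet. Record ids are taken
#' as the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`. Nucleotide sequences must
#'   contain only A/C/G/U after normalization; proteins the 20 standard
#'   residues plus `X`.
#' @param ambiguity What to do with IUPAC ambiguity codes in nucleotide
#'   input: `"error"` (default) rejects them, `"mask"` replaces them with
#'   `N` (ORFs overlapping `N` are discarded by the ORF caller).
#' @return A named character vector of normalized sequences, one element per
#'   record, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">v1", "acgt"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein"),
                       ambiguity = c("error", "mask")) {
  alphabet <- match.arg(alphabet)
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- gsub("[[:space:]]", "", toupper(as.character(set)))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  if (alphabet == "nucleotide") {
    seqs <- chartr("T", "U", seqs)
    ok <- c("A", "C", "G", "U")
    amb <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
    for (i in seq_along(seqs)) {
      ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
      bad <- which(!ch %in% ok)
      if (length(bad) > 0L) {
        if (ambiguity == "mask" && all(ch[bad] %in% amb)) {
          ch[bad] <- "N"
          seqs[[i]] <- paste(ch, collapse = "")
        } else {
          stop("illegal character '", ch[bad[1]], "' at position ", bad[1],
               " in nucleotide record '", ids[i], "'")
        }
      }
    }
  } else {
    ok <- c(AA20, "X")
    for (i in seq_along(seqs)) {
      ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
      bad <- which(!ch %in% ok)
      if (length(bad) > 0L) {
        stop("illegal character '", ch[bad[1]], "' at position ", bad[1],
             " in protein record '", ids[i], "'")
      }
    }
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width; `Inf` writes each sequence on one line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' Read an aligned FASTA (seed motif alignment)
#'
#' Like [read_fasta()] for proteins but allows the gap character `-` and
#' checks that all rows have equal length.
#'
#' @param path Path to an aligned protein FASTA.
#' @return Named character vector of equal-length aligned rows.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in alignment file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate sequence id(s) in alignment")
  aln <- gsub("[[:space:]]", "", toupper(as.character(set)))
  names(aln) <- ids
  if (length(unique(nchar(aln))) != 1L) {
    stop("ragged alignment: rows differ in length")
  }
  ok <- c(AA20, "X", "-", ".")
  for (i in seq_along(aln)) {
    ch <- strsplit(aln[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% ok)
    if (length(bad) > 0L) {
      stop("illegal character '", ch[bad[1]], "' at position ", bad[1],
           " in aligned record '", ids[i], "'")
    }
  }
  chartr(".", "-", aln)
}

#' Read a metadata table (TSV)
#'
#' @param path Path to a tab-separated file with a header row.
#' @param required Column names that must be present.
#' @return A `data.frame` with one row per input row; empty strings in
#'   optional columns are recorded as `NA`.
#' @export
read_metadata <- function(path,
                          required = c("library_id", "site_id")) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' Write a result table as TSV
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Reverse complement of an RNA sequence
#'
#' @param seq RNA string over A/C/G/U (N allowed).
#' @return The reverse complement as an RNA string.
#' @export
reverse_complement <- function(seq) {
  ch <- chartr("ACGUN", "UGCAN", seq)
  vapply(ch, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
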
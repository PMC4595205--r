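# FASTA / paired FASTQ ingest, pairing, and the N filter.
#
# References are plain named character vectors (name = first token of the
# header); read pairs are a data.frame with one row per pair. Coordinates are
# 0-based half-open everywhere inside the package; files written for users are
# 1-based inclusive.

#' Read a reference FASTA
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return Named character vector of upper-cased sequences; names are the
#'   first whitespace-delimited token of each header, order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                error = function(e) stop("malformed FASTA: ", conditionMessage(e),
                                         call. = FALSE))
  if (length(x) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  seqs <- toupper(as.character(x))
  names(seqs) <- vapply(strsplit(names(x), "[ \t]+"), `[`, character(1), 1L)
  if (anyNA(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("FASTA record with empty header", call. = FALSE)
  }
  .validate_dna(seqs, "reference")
  seqs
}

#' Write a reference FASTA
#'
#' @param reference Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

# strip a trailing mate suffix ("/1", "/2", " 1:...", ".1") from a read id
.strip_mate_suffix <- function(id) {
  sub("(/[12]|[ _][12](:[^ ]*)?|\\.[12])$", "", id)
}

#' Read paired FASTQ files into a read-pair table
#'
#' Records are paired by order; the pair id is the read id with its mate
#' suffix (`/1`, `/2`, ...) stripped. All reads must share one length.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2 (gzip accepted).
#' @param read_len Expected read length; `NULL` skips the check beyond
#'   requiring a single common length.
#' @return A `data.frame` with columns `pair_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2, read_len = NULL) {
  rd <- function(p) {
    if (!file.exists(p)) stop("FASTQ file not found: ", p, call. = FALSE)
    Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
  }
  x1 <- rd(path1); x2 <- rd(path2)
  if (length(x1) != length(x2)) {
    stop(sprintf("pairing error: %d records in %s vs %d in %s",
                 length(x1), path1, length(x2), path2), call. = FALSE)
  }
  id1 <- .strip_mate_suffix(vapply(strsplit(names(x1), "[ \t]"), `[`, character(1), 1L))
  id2 <- .strip_mate_suffix(vapply(strsplit(names(x2), "[ \t]"), `[`, character(1), 1L))
  if (!all(id1 == id2)) {
    k <- which(id1 != id2)[1]
    stop(sprintf("pairing error: record %d ids differ after suffix stripping ('%s' vs '%s')",
                 k, id1[k], id2[k]), call. = FALSE)
  }
  pairs <- data.frame(
    pair_id = id1,
    seq1 = toupper(as.character(x1)),
    qual1 = as.character(S4Vectors::mcols(x1)$qualities),
    seq2 = toupper(as.character(x2)),
    qual2 = as.character(S4Vectors::mcols(x2)$qualities),
    stringsAsFactors = FALSE
  )
  validate_read_pairs(pairs, read_len = read_len)
  pairs
}

#' Validate a read-pair table
#'
#' Checks the pair invariants: unique ids, one common read length for both
#' mates (optionally a required length), qualities matching sequence lengths.
#'
#' @param pairs Read-pair `data.frame` (see [read_fastq_pairs()]).
#' @param read_len Required read length or `NULL`.
#' @return `pairs`, invisibly.
#' @export
validate_read_pairs <- function(pairs, read_len = NULL) {
  need <- c("pair_id", "seq1", "qual1", "seq2", "qual2")
  if (!all(need %in% names(pairs))) {
    stop("read-pair table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pairs) == 0L) return(invisible(pairs))
  if (anyDuplicated(pairs$pair_id)) {
    stop("duplicate pair_id: ", pairs$pair_id[anyDuplicated(pairs$pair_id)],
         call. = FALSE)
  }
  l1 <- nchar(pairs$seq1); l2 <- nchar(pairs$seq2)
  lens <- unique(c(l1, l2))
  if (length(lens) != 1L) {
    stop("mixed read lengths are not supported (found ",
         paste(sort(lens), collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(read_len) && lens != read_len) {
    stop(sprintf("read length %d does not match configured length %d",
                 lens, read_len), call. = FALSE)
  }
  if (any(nchar(pairs$qual1) != l1) || any(nchar(pairs$qual2) != l2)) {
    stop("quality string length differs from sequence length", call. = FALSE)
  }
  .validate_dna(pairs$seq1, "read1"); .validate_dna(pairs$seq2, "read2")
  invisible(pairs)
}

#' Write a read-pair table to two FASTQ files
#'
#' Read ids are `<pair_id>/1` and `<pair_id>/2`.
#'
#' @param pairs Read-pair `data.frame`.
#' @param path1,path2 Output FASTQ paths.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  wr <- function(seqs, quals, ids, p) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, p, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  wr(pairs$seq1, pairs$qual1, paste0(pairs$pair_id, "/1"), path1)
  wr(pairs$seq2, pairs$qual2, paste0(pairs$pair_id, "/2"), path2)
  invisible(c(path1, path2))
}

#' Remove read pairs containing N
#'
#' A pair is removed when either mate contains at least one `N`; ambiguous
#' bases would otherwise distort the exact-match accounting downstream. The
#' whole pair is dropped so that all later statistics stay per-pair.
#'
#' @param pairs Read-pair `data.frame`.
#' @return List with `kept` (filtered table) and `removed` (count).
#' @export
filter_n_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(list(kept = pairs, removed = 0L))
  has_n <- grepl("N", pairs$seq1, fixed = TRUE) | grepl("N", pairs$seq2, fixed = TRUE)
  list(kept = pairs[!has_n, , drop = FALSE], removed = sum(has_n))
}
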
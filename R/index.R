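# Exact-match k-mer reference index.
#
# Stands in for a full read mapper with a deterministic decision contract:
# only forward-strand k-mer occurrences are stored; minus-strand hits are
# obtained by querying the reverse complement.

#' Build an exact-match k-mer index over a reference
#'
#' Every forward-strand k-mer occurrence containing no `N` is indexed.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param k Seed length in nt (default 30).
#' @return A `reference_index` object.
#' @export
build_index <- function(reference, k = 30L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (length(reference) == 0L) stop("reference is empty", call. = FALSE)
  lens <- nchar(reference)
  if (k > min(lens)) {
    stop(sprintf("k = %d exceeds the shortest reference sequence (%d nt)",
                 k, min(lens)), call. = FALSE)
  }
  parts <- lapply(names(reference), function(ch) {
    s <- reference[[ch]]
    n <- nchar(s)
    starts <- seq_len(n - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    keep <- !grepl("N", km, fixed = TRUE)
    data.table::data.table(kmer = km[keep], chrom = ch, pos = starts[keep] - 1L)
  })
  dt <- data.table::rbindlist(parts)
  data.table::setkeyv(dt, c("kmer", "chrom", "pos"))
  structure(list(k = k, dt = dt), class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat(sprintf("reference_index: k = %d, %d k-mer occurrences, %d distinct k-mers\n",
              x$k, nrow(x$dt), length(unique(x$dt$kmer))))
  invisible(x)
}

# forward-strand occurrences of `queries` (character vector, each of length k);
# returns data.table(qid, chrom, pos) sorted by (qid, chrom, pos)
.lookup_fwd <- function(index, queries) {
  q <- data.table::data.table(kmer = queries, qid = seq_along(queries))
  hit <- index$dt[q, on = "kmer", nomatch = NULL]
  data.table::setorderv(hit, c("qid", "chrom", "pos"))
  hit[, c("qid", "chrom", "pos")]
}

#' Map a k-length query exactly on both strands
#'
#' Minus-strand hits come from looking up the reverse complement; `pos` is
#' always the 0-based forward-strand left end of the k-window, so the oriented
#' reference substring at (`chrom`, `pos`, `strand`) equals the query.
#'
#' @param index A `reference_index`.
#' @param query A single sequence of length `index$k`.
#' @return `data.frame(chrom, pos, strand)` ordered by (chrom, pos, strand);
#'   zero rows when the query is absent.
#' @export
map_exact <- function(index, query) {
  if (nchar(query) != index$k) {
    stop(sprintf("query length %d != index k %d", nchar(query), index$k),
         call. = FALSE)
  }
  fwd <- .lookup_fwd(index, query)
  rev <- .lookup_fwd(index, revcomp(query))
  out <- rbind(
    data.frame(chrom = fwd$chrom, pos = fwd$pos, strand = rep("+", nrow(fwd)),
               stringsAsFactors = FALSE),
    data.frame(chrom = rev$chrom, pos = rev$pos, strand = rep("-", nrow(rev)),
               stringsAsFactors = FALSE)
  )
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

#' Extract the anchoring seed of a read
#'
#' Seeds are the 5'-most `seed_len` bases: extension proceeds rightward along
#' the read, so the anchor must sit at its start.
#'
#' @param read Read sequence.
#' @param seed_len Seed length in nt (default 30).
#' @return The seed string.
#' @export
extract_seed <- function(read, seed_len = 30L) {
  seed_len <- as.integer(seed_len)
  if (seed_len < 1L) stop("seed_len must be >= 1", call. = FALSE)
  if (nchar(read) < seed_len) {
    stop(sprintf("read length %d shorter than seed length %d",
                 nchar(read), seed_len), call. = FALSE)
  }
  substr(read, 1L, seed_len)
}
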
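# Low-level DNA string helpers shared across modules.
#
# Hot paths (seed extension, overlap calling) operate on raw byte vectors so
# that per-base comparisons stay vectorized; the rest of the package works with
# plain upper-case character strings.

# let data.table find its own [ methods when called from this namespace
.datatable.aware <- TRUE

# complement lookup over raw bytes; non-ACGTN bytes map to themselves
.COMP_TABLE <- local({
  tab <- as.raw(0:255)
  from <- utf8ToInt("ACGTNacgtn")
  to   <- utf8ToInt("TGCANtgcan")
  tab[from + 1L] <- as.raw(to)
  tab
})

#' Reverse complement of DNA strings
#'
#' Vectorized over its input; `N` is preserved, case is preserved.
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp(c("ACGT", "AANC"))
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    r <- rev(.COMP_TABLE[as.integer(charToRaw(s)) + 1L])
    rawToChar(r)
  }, character(1), USE.NAMES = FALSE)
}

# complement of a raw byte vector, order preserved
.comp_raw <- function(r) .COMP_TABLE[as.integer(r) + 1L]

# length of the initial run of equal bytes between two raw vectors
.match_run <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  eq <- a[seq_len(n)] == b[seq_len(n)]
  m <- match(FALSE, eq)
  if (is.na(m)) n else m - 1L
}

# A reference handle caches the raw bytes of each chromosome next to the
# character form, so repeated slicing does not re-encode the whole sequence.
.ref_handle <- function(reference) {
  if (inherits(reference, "chimera_ref")) return(reference)
  stopifnot(is.character(reference), !is.null(names(reference)),
            all(nzchar(names(reference))))
  h <- list(
    seq = reference,
    raw = lapply(reference, charToRaw),
    len = vapply(reference, nchar, integer(1))
  )
  class(h) <- "chimera_ref"
  h
}

# forward-strand raw slice of chromosome `chrom`, 0-based half-open [start, end)
.ref_raw <- function(refh, chrom, start, end) {
  start <- max(start, 0L)
  end <- min(end, refh$len[[chrom]])
  if (end <= start) return(raw(0))
  refh$raw[[chrom]][(start + 1L):end]
}

# oriented raw slice: strand "+" reads [start, end) left-to-right; strand "-"
# returns the reverse complement of the same forward window
.ref_raw_oriented <- function(refh, chrom, start, end, strand) {
  r <- .ref_raw(refh, chrom, start, end)
  if (strand == "-") rev(.comp_raw(r)) else r
}

.validate_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N} (first offender: %s)",
                 what, x[which(bad)[1]][1]), call. = FALSE)
  }
  invisible(TRUE)
}

# round half up to `digits` decimals (printed-table convention)
.round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
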
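# Pipeline configuration.

#' Resolver / pipeline configuration
#'
#' Tunable parameters of the subsection-alignment pipeline.
#'
#' @param seed_len Anchor seed length in nt; seeds are the 5'-most bases of
#'   each read.
#' @param window Half-width (bp) of the local region searched for the
#'   following subsection, upstream and downstream of the former subsection's
#'   end coordinate.
#' @param min_following_len Minimum unplaced-suffix length (nt) required to
#'   attempt relocation; also the probe length used for the window search.
#'   Bounds spurious exact matches of very short suffixes.
#' @param max_junctions Maximum junctions resolved per read; deeper reads are
#'   truncated with status `"partial"`.
#' @param read_len Expected read length in nt.
#' @param max_mismatch Mismatches tolerated in full-length placement
#'   (exact-match contract; only 0 is supported).
#' @param concordance_range Length-2 numeric: inner-distance interval (nt,
#'   gap between mates) accepted as a concordant pair. Default is the library
#'   mean +/- 4 SD for a 300 +/- 30 nt inner insert.
#' @return A `resolver_config` list.
#' @export
resolver_config <- function(seed_len = 30L,
                            window = 5000L,
                            min_following_len = 15L,
                            max_junctions = 3L,
                            read_len = 101L,
                            max_mismatch = 0L,
                            concordance_range = c(300 - 4 * 30, 300 + 4 * 30)) {
  cfg <- list(
    seed_len = as.integer(seed_len),
    window = as.integer(window),
    min_following_len = as.integer(min_following_len),
    max_junctions = as.integer(max_junctions),
    read_len = as.integer(read_len),
    max_mismatch = as.integer(max_mismatch),
    concordance_range = as.numeric(concordance_range)
  )
  stopifnot(cfg$seed_len >= 1L, cfg$window >= 1L, cfg$min_following_len >= 1L,
            cfg$max_junctions >= 1L, cfg$read_len >= cfg$seed_len,
            length(cfg$concordance_range) == 2L,
            cfg$concordance_range[1] <= cfg$concordance_range[2])
  if (cfg$max_mismatch != 0L) {
    stop("only exact full-length placement (max_mismatch = 0) is implemented",
         call. = FALSE)
  }
  class(cfg) <- "resolver_config"
  cfg
}
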
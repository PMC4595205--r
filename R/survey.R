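# Published pair counts used in worked examples.

#' Chimera counts from a published large-scale human MDA survey
#'
#' Per-sample read-pair accounting reported by a reanalysis of two human
#' whole-genome phi29 MDA sequencing libraries (PE-101, 131.4 Gb of clean
#' reads): total pairs and 1/2/3-level chimeric pair counts. Useful as worked
#' examples for [chimera_rate()] and [level_proportions()].
#'
#' @return `data.frame` with columns `sample` (`sampleA`, `sampleB`),
#'   `total_pairs`, `level1`, `level2`, `level3`.
#' @export
phi29_survey_counts <- function() {
  data.frame(
    sample = c("sampleA", "sampleB"),
    total_pairs = c(386293846, 264136965),
    level1 = c(23872631, 14992729),
    level2 = c(564397, 445861),
    level3 = c(158372, 225448),
    stringsAsFactors = FALSE
  )
}
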
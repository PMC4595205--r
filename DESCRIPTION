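Package: chimeraMDA
Title: Detection and Structural Characterization of phi29 MDA Chimeric Read Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers and structurally characterizes chimeric paired-end reads
    produced by phi29 multiple displacement amplification (MDA). Implements a
    subsection-alignment pipeline: exact seed mapping against a k-mer reference
    index, base-by-base seed extension to the first mismatch, windowed local
    relocation of the unplaced suffix, reverse extension to call microhomology
    (overlap) length, and the signed chimeric distance between adjacent
    subsections. Read pairs are classified into the MDA chimera taxonomy
    (insertion vs pair-end, inverted vs direct, chimerism level 1-3) and
    summarized with abundance distributions, orientation and level proportions,
    chimera rates, and the insert-size regression. A paired-end MDA read
    simulator with planted microhomologies and exact per-junction ground truth
    makes every stage testable end-to-end, backed by independent brute-force
    oracles for overlap calling and read resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    data.table,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
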
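---
title: "Detecting phi29 MDA chimeras: model, algorithm and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phi29 MDA chimeras: model, algorithm and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraMDA)
```

## The problem

Multiple displacement amplification (MDA) with phi29 polymerase is the
standard way to amplify femtograms of DNA into sequencing-library quantities.
Its price is *chimera formation*: during strand displacement the polymerase
can dissociate from its template and re-prime on a nearby single-stranded
region, producing molecules whose parts map to inconsecutive — but adjacent —
reference loci. In paired-end sequencing data, a chimeric molecule shows up in
one of two ways:

* **pair-end chimera** — the junction falls inside a sequenced read, so the
  read itself is split into two or more *subsections* mapping to different
  places;
* **insertion chimera** — the junction falls in the unsequenced inner insert:
  both reads map full length individually, but the pair violates paired-end
  geometry (wrong chromosome, wrong strand combination, reversed order, or an
  inner distance outside the expected range).

A pair can carry several junctions. We call the number of chimeric events in a
pair its **level** (reported as 1, 2, or 3+, capped at 3), and a pair *mixed*
when it has both a visible read junction and an inferred insert junction.

Each junction is characterized by:

* the **orientation**: *inverted* when the two subsections map to opposite
  strands, *direct* otherwise;
* the **chimeric distance** `D = C_former_end − C_following_start`, the signed
  difference between the forward-strand coordinate of the last template base
  of the former subsection and the first template base of the following
  subsection;
* the **overlap**: the length of microhomology — the reference bases
  immediately preceding the following subsection's start that repeat the tail
  of the former subsection. Re-priming favours a few bases of complementarity,
  so overlaps concentrate around ~6 nt.

## Detection algorithm

Detection uses two exact-mapping passes over a k-mer index of the reference:

1. **Full-length pass.** Each 101-nt read is placed exactly (both strands).
   Pairs placing concordantly are non-chimeric. Pairs whose reads both place
   full-length but discordantly are insertion-chimera candidates.
2. **Seed pass.** For every read that did not place full length, its 5′-most
   30-nt *seed* is placed. Reads with a uniquely placed seed but no full-length
   placement are junction candidates.

For every candidate read the resolver then repeats:

* **extend** — starting from the seed placement, extend the match base by base
  along the template until the first mismatch. This yields the former
  subsection and the read offset of the putative junction.
* **locate** — take the first 15 nt of the remaining suffix as an exact probe
  and search for it on both strands within ±5,000 bp of the former
  subsection's end coordinate. Each hit is extended to its maximal length.
* **choose** — among placements, keep the longest extension; ties are broken
  by smallest `|D|`, then by preferring the '+' strand. Placements still tied
  after that make the read *ambiguous* and it is excluded from accounting.
  (The tie policy is a package convention; exact ties are rare in practice.)
* **overlap** — extend the match *backwards* from the junction: compare the
  former subsection's tail with the oriented reference window preceding the
  following subsection's start. The length of agreement is the microhomology.

The loop continues with the following subsection as the new former until the
read is consumed (`full`), the suffix is shorter than the probe or no in-window
placement exists (`partial`), or the junction cap (3) is reached. All internal
coordinates are 0-based half-open; files written by the pipeline use 1-based
inclusive coordinates.

An independent *oracle* implementation (`oracle_resolve()`), written with
naive character-level loops and no shared helpers, re-states the same
procedure and is used in the test suite to validate the vectorized resolver on
random references.

## Classification and statistics

`classify_dataset()` combines per-read junction counts with the insert
geometry check into the pair-level taxonomy (level 1/2/3 ×
insertion/pair-end/mixed). The statistics layer provides per-nt abundance
histograms of `|D|` and overlap, orientation and level proportions, the
chimera rate, and the regression of the insertion:pair-end ratio on mean
insert size. Printed percentages use half-up rounding to two decimals, the
convention of published survey tables; `phi29_survey_counts()` ships the pair
counts of a published large-scale human MDA survey so that this arithmetic is
reproducible.

With reads of length `R = 101` and an inner insert of length `i`, a junction
falling uniformly on the fragment lands in a read window with probability
`2R/(i + 2R)` and in the insert otherwise, so the expected insertion:pair-end
ratio is approximately `i / 2R = i / 202` — a linear function of insert size.
This geometric identity is one of the package's acceptance properties.

## Simulator design

`simulate_dataset()` generates a random reference and paired 101-nt reads from
fragments with a normal inner insert (default 300 ± 30 nt). A configurable
fraction of fragments is chimeric; per chimeric fragment the number of
junctions is drawn from the level distribution (defaults 0.9706 / 0.0229 /
0.0064, renormalized), each junction's signed distance from a truncated
two-component mixture (main mode near 275 nt, a broad secondary component),
its orientation from `p_inverted = 0.707`, and its overlap from a discretized
normal with mode 6. These defaults are the package's model of the study
conditions and are fixed independently of any test outcome.

Two design points matter for exact ground truth:

* **Planted microhomology.** Random sequence essentially never provides a
  5–8 nt homology at a chosen distance, so the simulator *plants* it: before
  the reference is frozen, the oriented tail of the former subsection is
  copied into the window preceding the following subsection's start. The two
  boundary bases are then forced to mismatch (the base before the planted
  window, and the former subsection's continuation base), so the realized
  homology equals the planted draw exactly and the breakpoint is unambiguous.
  When a subsection is shorter than the draw the realized overlap is capped at
  the subsection length; truth tables always store the realized value,
  computed by an independent brute-force oracle (`oracle_overlap()`).
  An occupancy map prevents one pair's plant from corrupting another pair's
  template; placements are retried when they collide.
* **Observation frame.** Junctions visible in read 2 are observed on the
  reverse-complemented strand, so truth rows swap former/following, flip
  strands and negate `D` for that frame. Detected calls and truth therefore
  share one coordinate convention and can be compared field by field.

Degenerate "junctions" that reconstruct contiguous reference (`D = −1` on '+',
`D = +1` on '−' with equal strands) are rejected and redrawn.

The `junction_region` switch controls where junctions fall on the fragment:
`"fragment"` (uniform — the natural model, used for the insert-size linearity
property) or `"read"` (restricted to read windows — used for recovery
benchmarks, where junctions must be visible to be recoverable).

## Recovery metrics and detectability

`junction_recovery()` scores detected calls against truth. A truth junction is
*eligible* when the whole junction chain of its observing read is resolvable:
the 30-nt seed avoids the first junction, every subsequent subsection offers
at least 15 bases before the next junction, and the final suffix is at least
15 nt. Junctions failing these bounds (for example a 6-nt middle subsection
between two close junctions) cannot be recovered by this method as a matter of
principle, and are reported as ineligible rather than as detection misses.
*Sensitivity* is the detected fraction of eligible junctions; *exactness* is
the fraction of all calls matching truth exactly in breakpoint coordinates,
signed distance and realized overlap.

## Numerical and scale choices

Problem sizes used in the tests and the acceptance run are the package's own
choices, selected to give stable statistics on one CPU in minutes: recovery
runs use 2,000 chimeric pairs on a 200-kb reference; orientation and overlap
recovery use ~9,000 pairs on a 2-Mb reference, yielding over 5,000 detected
junctions (±0.02 is about three binomial standard deviations for the inverted
fraction at that size); the insert-size regression uses eight subsamples of
2,500 pairs with mean inner inserts 100–450 nt. Hot paths (seed extension,
overlap measurement) compare raw byte vectors; the k-mer index is a keyed
`data.table`.

## Limitations

* Mapping is exact-match; the simulator's default error rate is 0. With real,
  error-containing reads the seed/extension steps would need a mismatch
  budget, which changes candidate selection.
* Only one insert junction per pair is inferable from geometry, so deep
  chimeras whose extra junctions all fall in the insert are undercounted and
  `mixed` is a lower bound — a limitation shared by any read-pair method.
* Junction chains with subsections shorter than the 15-nt probe are
  unresolvable by design; they are quantified via the eligibility definition
  above.
* The distance and overlap models are qualitative mimics of published
  empirical distributions (bimodal distance with a main mode near 250–300 nt;
  overlap mode 6 nt), not fits: the exact generating distributions are not
  recoverable from published figures.
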
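test_that("simulation is fully reproducible from the seed", {
  cfg <- sim_config(ref_length = 20000L, n_pairs = 30L, chimera_fraction = 0.5,
                    junction_region = "read", seed = 77L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$reference, b$reference)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$truth_pairs, b$truth_pairs)
  expect_identical(a$truth_junctions, b$truth_junctions)
})

test_that("planted homology copies the source window, inverted on request", {
  plants <- list(list(loci = c(500L, 1200L), o = 8L, inverted = FALSE),
                 list(loci = c(700L, 1600L), o = 6L, inverted = TRUE))
  ref <- make_reference(2000L, seed = 5L, homology_plants = plants)
  s <- unname(ref)
  expect_identical(substr(s, 1200L - 8L + 1L, 1200L),
                   substr(s, 500L - 8L + 1L, 500L))
  expect_identical(substr(s, 1600L - 6L + 1L, 1600L),
                   revcomp(substr(s, 700L - 6L + 1L, 700L)))
  expect_error(make_reference(2000L, homology_plants =
    list(list(loci = c(100L, 300L), o = 4L),
         list(loci = c(200L, 300L), o = 4L))), "overlapping")
})

test_that("reads are the fragment ends and non-chimeric fragments match the reference", {
  sim <- small_sim()
  # every read is 101 nt with clean bases
  expect_true(all(nchar(sim$pairs$seq1) == 101L))
  expect_true(all(nchar(sim$pairs$seq2) == 101L))
  expect_false(any(grepl("[^ACGT]", c(sim$pairs$seq1, sim$pairs$seq2))))

  cfg0 <- sim_config(ref_length = 20000L, n_pairs = 20L,
                     chimera_fraction = 0, seed = 13L)
  plain <- simulate_dataset(cfg0)
  expect_true(all(!plain$truth_pairs$is_chimera))
  # a non-chimeric read1 occurs verbatim in the reference
  expect_true(all(vapply(plain$pairs$seq1, function(r)
    grepl(r, unname(plain$reference), fixed = TRUE), logical(1))))
})

test_that("boundary forcing pins realized overlap at the planted draw", {
  sim <- small_sim()
  tj <- sim$truth_junctions
  expect_gt(nrow(tj), 100L)
  # forcing the boundary bases to mismatch means homology never exceeds the
  # planted length
  expect_true(all(tj$realized_overlap <= tj$planted_overlap))
  # it can only fall short when the former subsection is shorter than the
  # draw (the cap); with both flanking pieces longer than any draw the
  # realized overlap is exactly the planted one
  nj <- sim$truth_pairs$n_junctions[match(tj$pair_id, sim$truth_pairs$pair_id)]
  fl <- sim$truth_pairs$fragment_len[match(tj$pair_id, sim$truth_pairs$pair_id)]
  cfg <- sim_config()
  long <- nj == 1L & tj$frag_offset >= cfg$overlap_max &
    (fl - tj$frag_offset) >= cfg$overlap_max
  expect_gt(sum(long), 50L)
  expect_identical(tj$realized_overlap[long], tj$planted_overlap[long])
})

test_that("truth junction coordinates are verified by the overlap oracle and distance identity", {
  sim <- small_sim()
  tj <- sim$truth_junctions
  expect_identical(tj$distance, tj$former_end_coord - tj$following_start_coord)
  expect_identical(tj$orientation == "inverted",
                   tj$former_strand != tj$following_strand)
  # no degenerate direct junctions (contiguous reference)
  degen <- (tj$orientation == "direct") &
    ((tj$former_strand == "+" & tj$distance == -1L) |
     (tj$former_strand == "-" & tj$distance == 1L))
  expect_false(any(degen))
})

test_that("truth-level mixture follows the configured probabilities", {
  cfg <- sim_config(ref_length = 400000L, n_pairs = 1500L,
                    chimera_fraction = 1, junction_region = "read",
                    seed = 33L)
  sim <- simulate_dataset(cfg)
  nj <- sim$truth_pairs$n_junctions
  p <- cfg$level_probs / sum(cfg$level_probs)
  obs <- vapply(1:3, function(k) sum(nj == k), numeric(1))
  cs <- suppressWarnings(stats::chisq.test(obs, p = p))
  expect_gt(cs$p.value, 1e-4)
})

test_that("chimera fraction controls the share of chimeric pairs", {
  cfg <- sim_config(ref_length = 100000L, n_pairs = 400L,
                    chimera_fraction = 0.25, seed = 55L)
  sim <- simulate_dataset(cfg)
  frac <- mean(sim$truth_pairs$is_chimera)
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.35)
})
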
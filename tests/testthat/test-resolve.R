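test_that("extend_match stops at the first mismatch on the plus strand", {
  tp <- build_two_part_read(a_len = 60L, b_strand = "+")
  e <- extend_match(tp$read, 0L, "chr1", tp$a, "+", tp$reference,
                    anchor_len = 30L)
  expect_identical(e, tp$a_len)
})

test_that("extend_match handles minus-strand anchors", {
  set.seed(31)
  chars <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
  ref <- c(chr1 = paste0(chars, collapse = ""))
  # read = revcomp of ref[500, 560): anchored minus-strand seed extends to 60
  read_part <- revcomp(substr(unname(ref), 501, 560))
  filler <- substr(unname(ref), 1001, 1041)
  read <- paste0(read_part, filler)
  # the 30-nt seed of the read corresponds to forward window [530, 560)
  e <- extend_match(read, 0L, "chr1", 530L, "-", ref, anchor_len = 30L)
  expect_gte(e, 60L)
})

test_that("signed chimeric distance follows the coordinate convention", {
  former <- list(chrom = "chr1", ref_start = 100L, ref_end = 160L, strand = "+")
  following <- list(chrom = "chr1", ref_start = 400L, ref_end = 440L, strand = "+")
  # former end coordinate = 159, following start coordinate = 400
  expect_identical(chimeric_distance(former, following), 159L - 400L)
  inv <- list(chrom = "chr1", ref_start = 400L, ref_end = 440L, strand = "-")
  # on '-' the following starts at its rightmost forward coordinate, 439
  expect_identical(chimeric_distance(former, inv), 159L - 439L)
  other <- list(chrom = "chr2", ref_start = 0L, ref_end = 40L, strand = "+")
  expect_true(is.na(chimeric_distance(former, other)))
})

test_that("compute_overlap matches the brute-force oracle on planted homology", {
  # plant a 5-mer homology: window before the following start repeats the
  # former tail
  plants <- list(list(loci = c(300L, 900L), o = 5L, inverted = FALSE))
  ref <- make_reference(2000L, seed = 41L, homology_plants = plants)
  former <- list(chrom = "chr1", ref_start = 240L, ref_end = 300L,
                 strand = "+", read_start = 0L, read_end = 60L)
  following <- list(chrom = "chr1", ref_start = 900L, ref_end = 941L,
                    strand = "+", read_start = 60L, read_end = 101L)
  got <- compute_overlap(former, following, ref)
  want <- oracle_overlap(ref, former, following)
  expect_identical(got, want)
  expect_gte(got, 5L)
})

test_that("resolve_read recovers a constructed direct junction exactly", {
  tp <- build_two_part_read(a = 200L, a_len = 60L, b = 700L, b_strand = "+")
  res <- resolve_read(tp$read, tp$anchor, tp$reference, resolver_config())
  expect_identical(res$status, "full")
  expect_identical(nrow(res$junctions), 1L)
  j <- res$junctions
  expect_identical(j$former_end_coord, tp$a + tp$a_len - 1L)
  expect_identical(j$following_start_coord, tp$b)
  expect_identical(j$orientation, "direct")
  # segments tile the read exactly
  expect_identical(res$segments$read_start[1], 0L)
  expect_identical(res$segments$read_end[nrow(res$segments)], 101L)
  expect_identical(sum(res$segments$read_end - res$segments$read_start), 101L)
})

test_that("resolve_read recovers a constructed inverted junction exactly", {
  tp <- build_two_part_read(a = 150L, a_len = 55L, b = 900L, b_strand = "-",
                            seed = 17L)
  res <- resolve_read(tp$read, tp$anchor, tp$reference, resolver_config())
  expect_identical(res$status, "full")
  expect_identical(nrow(res$junctions), 1L)
  expect_identical(res$junctions$orientation, "inverted")
  expect_identical(res$junctions$following_strand, "-")
  expect_identical(res$junctions$following_start_coord, tp$b - 1L)
})

test_that("a read matching the reference end to end is not chimeric", {
  ref <- make_reference(2000L, seed = 51L)
  read <- substr(unname(ref), 501, 601)
  res <- resolve_read(read, list(chrom = "chr1", ref_start = 500L, strand = "+"),
                      ref, resolver_config())
  expect_identical(res$status, "not_chimeric")
  expect_identical(nrow(res$junctions), 0L)
})

test_that("relocation outside the window reports a partial resolution", {
  # following part placed 8000 bp away, beyond the +-5000 search window
  tp <- build_two_part_read(ref_len = 12000L, a = 500L, a_len = 60L,
                            b = 9000L, b_strand = "+", seed = 19L)
  res <- resolve_read(tp$read, tp$anchor, tp$reference, resolver_config())
  expect_identical(res$status, "partial")
  expect_identical(res$fail_reason, "out_of_window")
  expect_identical(res$unplaced_suffix_len, 41L)
})

test_that("two placements tied on extension, |D| and strand are ambiguous", {
  set.seed(61)
  bases <- c("A", "C", "G", "T")
  chars <- sample(bases, 3000, replace = TRUE)
  block <- sample(bases, 41, replace = TRUE)
  # stop the former extension exactly at the junction
  if (block[1] == chars[261]) block[1] <- setdiff(bases, chars[261])[1]
  # plant the suffix block symmetrically around the former end coordinate
  # (0-based 259): following starts 59 and 459 give |D| = 200 on both sides
  chars[60:100] <- block
  chars[460:500] <- block
  ref <- c(chr1 = paste0(chars, collapse = ""))
  read <- paste0(c(chars[201:260], block), collapse = "")
  anchor <- list(chrom = "chr1", ref_start = 200L, strand = "+")
  res <- resolve_read(read, anchor, ref, resolver_config())
  expect_identical(res$status, "ambiguous")
  ora <- oracle_resolve(read, anchor, ref, resolver_config())
  expect_identical(ora$status, "ambiguous")
})

test_that("resolver and oracle agree on simulated chimeric reads", {
  sim <- small_sim()
  cfg <- resolver_config()
  det <- small_detect()
  aln <- det$aln
  cand <- select_candidates(sim$pairs, aln)$candidates
  take <- head(seq_len(nrow(cand)), 40)
  for (i in take) {
    anchor <- list(chrom = cand$chrom[i], ref_start = cand$ref_start[i],
                   strand = cand$strand[i])
    a <- resolve_read(cand$seq[i], anchor, sim$reference, cfg)
    b <- oracle_resolve(cand$seq[i], anchor, sim$reference, cfg)
    expect_identical(a$status, b$status)
    expect_identical(a$segments, b$segments)
    if (nrow(a$junctions)) {
      expect_identical(a$junctions, b$junctions)
    } else {
      expect_true(is.null(b$junctions) ||
                  (is.data.frame(b$junctions) && nrow(b$junctions) == 0L))
    }
  }
})
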
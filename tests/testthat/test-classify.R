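test_that("insert discordance flags every violation and passes concordance", {
  rl <- 101L
  conc <- list(chrom = "chr1", pos = 1000L, strand = "+")
  mate <- list(chrom = "chr1", pos = 1401L, strand = "-")
  expect_false(detect_insert_discordance(conc, mate, rl)$flag)

  other <- list(chrom = "chr2", pos = 1401L, strand = "-")
  expect_identical(detect_insert_discordance(conc, other, rl)$reason,
                   "different_chrom")

  same <- list(chrom = "chr1", pos = 1401L, strand = "+")
  expect_identical(detect_insert_discordance(conc, same, rl)$reason,
                   "same_strand")

  rev1 <- list(chrom = "chr1", pos = 2000L, strand = "+")
  rev2 <- list(chrom = "chr1", pos = 100L, strand = "-")
  expect_identical(detect_insert_discordance(rev1, rev2, rl)$reason,
                   "reversed_order")

  far <- list(chrom = "chr1", pos = 5000L, strand = "-")
  expect_identical(detect_insert_discordance(conc, far, rl)$reason,
                   "inner_distance")
})

test_that("levels count chimeric events and types follow the taxonomy", {
  # non-chimeric pair
  c0 <- classify_pair(0L, 0L, FALSE)
  expect_false(c0$is_chimera)
  expect_true(is.na(c0$level))

  # one visible junction: level 1, pair-end
  c1 <- classify_pair(1L, 0L, FALSE)
  expect_identical(c1$level, 1L)
  expect_identical(c1$chimera_type, "pair_end")

  # insert junction only: level 1, insertion
  ci <- classify_pair(0L, 0L, TRUE)
  expect_identical(ci$level, 1L)
  expect_identical(ci$chimera_type, "insertion")

  # visible + insert: level 2, mixed
  cm <- classify_pair(1L, 0L, TRUE)
  expect_identical(cm$level, 2L)
  expect_identical(cm$chimera_type, "mixed")

  # deep chimeras cap at level 3
  c3 <- classify_pair(2L, 2L, TRUE)
  expect_identical(c3$level, 3L)

  # ambiguous resolutions are excluded from accounting
  ca <- classify_pair(1L, 0L, FALSE, resolution = "ambiguous")
  expect_true(is.na(ca$is_chimera))
})

test_that("dataset classification conserves the pair partition", {
  sim <- small_sim()
  det <- small_detect()
  cl <- det$classes
  expect_identical(nrow(cl), nrow(sim$pairs))
  n_chim <- sum(cl$is_chimera %in% TRUE)
  n_not <- sum(cl$is_chimera %in% FALSE)
  n_amb <- sum(is.na(cl$is_chimera))
  expect_identical(n_chim + n_not + n_amb, nrow(sim$pairs))
  lv <- level_proportions(cl)
  expect_identical(as.integer(sum(lv$count)), n_chim)
})
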
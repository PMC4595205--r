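test_that("chimera_rate and level_proportions reproduce printed-table arithmetic", {
  # published human MDA survey counts shipped with the package
  tab <- phi29_survey_counts()
  chim <- tab$level1 + tab$level2 + tab$level3
  rates <- chimera_rate(chim, tab$total_pairs)
  expect_identical(rates, c(6.37, 5.93))
  expect_identical(chimera_rate(sum(chim), sum(tab$total_pairs)), 6.19)
  lp1 <- level_proportions(c(tab$level1[1], tab$level2[1], tab$level3[1]))
  lp2 <- level_proportions(c(tab$level1[2], tab$level2[2], tab$level3[2]))
  expect_identical(lp1$percent[1], 97.06)
  expect_identical(lp2$percent[1], 95.71)
})

test_that("half-up rounding is used for printed percentages", {
  # 0.125 rounds up to 0.13 under the table convention (not banker's rounding)
  expect_identical(chimera_rate(125, 100000), 0.13)
})

test_that("histograms conserve counts and report the right mode", {
  jx <- data.frame(abs_distance = c(1L, 5L, 5L, 5L, 7000L),
                   overlap_len = c(0L, 6L, 6L, 2L, 6L),
                   orientation = c("direct", "inverted", "inverted",
                                   "direct", "inverted"))
  dh <- distance_histogram(jx, max_d = 5000L)
  expect_identical(sum(dh$counts) + dh$n_excluded, nrow(jx))
  expect_identical(histogram_mode(dh), 5L)
  oh <- overlap_histogram(jx)
  expect_identical(sum(oh$counts), nrow(jx))
  expect_identical(histogram_mode(oh), 6L)
  op <- orientation_proportions(jx)
  expect_equal(unname(op["inverted"] + op["direct"]), 1)
})

test_that("insertion:pair-end ratio excludes mixed pairs", {
  cl <- data.frame(
    is_chimera = c(TRUE, TRUE, TRUE, TRUE, FALSE, NA),
    chimera_type = c("insertion", "insertion", "pair_end", "mixed", NA, NA),
    stringsAsFactors = FALSE
  )
  r <- insertion_pairend_ratio(cl)
  expect_identical(r$n_insertion, 2L)
  expect_identical(r$n_pair_end, 1L)
  expect_identical(r$n_mixed, 1L)
  expect_equal(r$ratio, 2)
})

test_that("regression on exactly linear points returns slope and R^2 of 1", {
  sub <- data.frame(mean_insert = c(100, 150, 200, 250, 300),
                    ratio = c(100, 150, 200, 250, 300) / 202)
  fit <- suppressWarnings(ratio_vs_insert_regression(sub))
  expect_equal(fit$slope, 1 / 202)
  expect_equal(fit$r_squared, 1)
  expect_identical(fit$n_points, 5L)
})
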
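# Results-layer statistics: abundance histograms of chimeric distance and
# overlap length, orientation and level proportions, chimera rates, and the
# insert-size vs insertion:pair-end ratio regression.

#' Histogram of absolute chimeric distance
#'
#' 1-nt bins over `[0, max_d]`. Junctions without a distance (cross-chromosome)
#' are excluded and counted.
#'
#' @param junctions Junction table with a `distance` (or `abs_distance`) column.
#' @param max_d Largest distance retained (default 5000, the search window).
#' @param bin_width Bin width in nt (default 1; re-binning is presentation
#'   only, raw counts are per-nt).
#' @return A `chimera_histogram` list: `bin_edges` (left edges), `counts`,
#'   `n_excluded`.
#' @export
distance_histogram <- function(junctions, max_d = 5000L, bin_width = 1L) {
  d <- if ("abs_distance" %in% names(junctions)) junctions$abs_distance
       else abs(junctions$distance)
  excl <- is.na(d) | d > max_d
  d <- d[!excl]
  edges <- seq(0L, max_d, by = bin_width)
  counts <- if (length(d)) {
    tabulate(findInterval(d, c(edges, max_d + 1L)), nbins = length(edges))
  } else {
    integer(length(edges))
  }
  structure(list(bin_edges = edges, counts = counts, n_excluded = sum(excl)),
            class = "chimera_histogram")
}

#' Histogram of overlap length
#'
#' 1-nt bins from 0 to the largest observed overlap.
#'
#' @param junctions Junction table with an `overlap_len` column.
#' @return A `chimera_histogram`; empty input gives an empty histogram.
#' @export
overlap_histogram <- function(junctions) {
  o <- junctions$overlap_len
  o <- o[!is.na(o)]
  if (!length(o)) {
    return(structure(list(bin_edges = integer(0), counts = integer(0),
                          n_excluded = 0L), class = "chimera_histogram"))
  }
  edges <- 0:max(o)
  counts <- tabulate(o + 1L, nbins = length(edges))
  structure(list(bin_edges = edges, counts = counts, n_excluded = 0L),
            class = "chimera_histogram")
}

#' Mode of a histogram
#'
#' @param h A `chimera_histogram`.
#' @return The left edge of the first bin with maximal count; `NA` when empty.
#' @export
histogram_mode <- function(h) {
  if (!length(h$counts) || sum(h$counts) == 0L) return(NA_integer_)
  h$bin_edges[which.max(h$counts)]
}

#' @export
print.chimera_histogram <- function(x, ...) {
  cat(sprintf("chimera_histogram: %d bins, %d observations (%d excluded), mode at %s\n",
              length(x$counts), sum(x$counts), x$n_excluded,
              format(histogram_mode(x))))
  invisible(x)
}

#' Orientation proportions among junctions
#'
#' @param junctions Junction table with an `orientation` column.
#' @return Named numeric: `inverted` and `direct` fractions (sum to 1).
#' @export
orientation_proportions <- function(junctions) {
  o <- junctions$orientation
  if (!length(o)) stop("no junctions: orientation proportions undefined",
                       call. = FALSE)
  c(inverted = mean(o == "inverted"), direct = mean(o == "direct"))
}

#' Per-level chimera counts and percentages
#'
#' Percentages are over chimeric pairs only, rounded half-up to two decimals
#' (printed-table convention).
#'
#' @param classes Classification `data.frame` (see [classify_dataset()]) or a
#'   named numeric vector of level counts.
#' @return `data.frame(level, count, percent)` plus a `total` attribute.
#' @export
level_proportions <- function(classes) {
  counts <- if (is.data.frame(classes)) {
    lv <- classes$level[!is.na(classes$is_chimera) & classes$is_chimera %in% TRUE]
    vapply(1:3, function(k) sum(lv == k, na.rm = TRUE), numeric(1))
  } else {
    as.numeric(classes)[1:3]
  }
  total <- sum(counts)
  pct <- if (total > 0) .round_half_up(100 * counts / total, 2L) else rep(NA_real_, 3)
  out <- data.frame(level = 1:3, count = counts, percent = pct)
  attr(out, "total") <- total
  out
}

#' Chimera rate as a printed percentage
#'
#' `100 * n_chimeric / n_total`, rounded half-up to two decimals.
#'
#' @param n_chimeric_pairs,n_total_pairs Pair counts (vectorized).
#' @return Percentage(s), numeric.
#' @export
chimera_rate <- function(n_chimeric_pairs, n_total_pairs) {
  if (any(n_total_pairs <= 0)) stop("total pair count must be positive", call. = FALSE)
  .round_half_up(100 * n_chimeric_pairs / n_total_pairs, 2L)
}

#' Ratio of insertion chimeras to pair-end chimeras
#'
#' Mixed pairs are excluded from the ratio and counted separately.
#'
#' @param classes Classification `data.frame`.
#' @return List: `ratio`, `n_insertion`, `n_pair_end`, `n_mixed`.
#' @export
insertion_pairend_ratio <- function(classes) {
  chim <- classes[!is.na(classes$is_chimera) & classes$is_chimera %in% TRUE, ,
                  drop = FALSE]
  n_ins <- sum(chim$chimera_type == "insertion")
  n_pe <- sum(chim$chimera_type == "pair_end")
  n_mix <- sum(chim$chimera_type == "mixed")
  if (n_pe == 0L) stop("no pair-end chimeras: ratio undefined", call. = FALSE)
  list(ratio = n_ins / n_pe, n_insertion = n_ins, n_pair_end = n_pe,
       n_mixed = n_mix)
}

#' Regression of insertion:pair-end ratio on mean insert size
#'
#' Ordinary least squares of the ratio on the mean insert size across
#' subsamples; `r_squared` is the squared Pearson correlation.
#'
#' @param subsamples `data.frame` with columns `mean_insert` and `ratio`.
#' @return List: `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
ratio_vs_insert_regression <- function(subsamples) {
  if (nrow(subsamples) < 3L) stop("need at least 3 subsamples", call. = FALSE)
  x <- subsamples$mean_insert; y <- subsamples$ratio
  if (stats::var(x) == 0) stop("zero variance in mean insert size", call. = FALSE)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n_points = nrow(subsamples))
}

#' Plot an abundance histogram
#'
#' Presentation-level re-binning of a distance/overlap histogram; raw counts
#' stay per-nt.
#'
#' @param h A `chimera_histogram`.
#' @param bin_width Plot bin width in nt.
#' @param xlab X-axis label.
#' @return A ggplot object.
#' @export
plot_histogram <- function(h, bin_width = 50L, xlab = "chimeric distance (nt)") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  bin <- (h$bin_edges %/% bin_width) * bin_width
  df <- stats::aggregate(list(count = h$counts), list(bin = bin), sum)
  ggplot2::ggplot(df, ggplot2::aes(x = bin, y = count)) +
    ggplot2::geom_col(width = bin_width * 0.9) +
    ggplot2::labs(x = xlab, y = "junctions") +
    ggplot2::theme_minimal()
}

#' Plot the ratio vs insert-size regression
#'
#' @param subsamples `data.frame(mean_insert, ratio)`.
#' @return A ggplot object with the fitted OLS line.
#' @export
plot_ratio_regression <- function(subsamples) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(subsamples, ggplot2::aes(x = mean_insert, y = ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "mean insert size (nt)",
                  y = "insertion : pair-end chimera ratio") +
    ggplot2::theme_minimal()
}
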
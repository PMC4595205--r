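# Orchestration: simulate -> detect -> stats, in memory and as file-based
# subcommand runners with a reproducible run manifest.
#
# File outputs are TSV with 1-based inclusive reference coordinates; internal
# tables stay 0-based half-open.

#' Detect and classify chimeras in a read-pair dataset
#'
#' End-to-end detection: N filtering, full-length and seed alignment passes,
#' candidate selection, junction resolution, insert-geometry check, and pair
#' classification.
#'
#' @param reference Named character vector.
#' @param pairs Read-pair `data.frame`.
#' @param config A [resolver_config()].
#' @return List: `classes` (pair classification table), `junctions` (junction
#'   calls, `NULL` when none), `reads` (per-candidate-read resolution
#'   statuses), `alignment_summary` (per-pass mapped/unmapped read counts),
#'   `counters` (dropped-category log: N-filtered pairs, ambiguous seeds,
#'   ambiguous resolutions, out-of-window and short suffixes), and `aln`
#'   (the `pair_alignment`).
#' @export
detect_chimeras <- function(reference, pairs, config = resolver_config()) {
  validate_read_pairs(pairs, read_len = config$read_len)
  flt <- filter_n_pairs(pairs)
  kept <- flt$kept
  refh <- .ref_handle(reference)
  if (nrow(kept) == 0L) {
    empty_classes <- data.frame(pair_id = character(0), is_chimera = logical(0),
                                level = integer(0), chimera_type = character(0),
                                n_read1_junctions = integer(0),
                                n_read2_junctions = integer(0),
                                insert_flag = logical(0),
                                resolution = character(0),
                                stringsAsFactors = FALSE)
    return(list(classes = empty_classes, junctions = NULL, reads = NULL,
                alignment_summary = data.frame(
                  pass = c("full_length", "seed"),
                  mapped = c(0L, 0L), unmapped = c(0L, 0L)),
                counters = c(n_filtered_pairs = flt$removed,
                             ambiguous_seeds = 0L, ambiguous_resolutions = 0L,
                             out_of_window = 0L, short_suffix = 0L),
                aln = NULL))
  }
  aln <- align_dataset(refh, kept, config)
  sel <- select_candidates(kept, aln)
  resolved <- resolve_candidates(sel$candidates, refh, config)
  classes <- classify_dataset(aln, resolved)
  st <- aln$status
  summary <- data.frame(
    pass = c("full_length", "seed"),
    mapped = c(sum(st$r1_n_full > 0L) + sum(st$r2_n_full > 0L),
               sum(st$r1_seed_n > 0L) + sum(st$r2_seed_n > 0L)),
    unmapped = c(sum(st$r1_n_full == 0L) + sum(st$r2_n_full == 0L),
                 sum(st$r1_seed_n == 0L) + sum(st$r2_seed_n == 0L))
  )
  rr <- resolved$reads
  counters <- c(
    n_filtered_pairs = flt$removed,
    ambiguous_seeds = sel$n_ambiguous_seeds,
    ambiguous_resolutions = if (is.null(rr)) 0L else sum(rr$status == "ambiguous"),
    out_of_window = if (is.null(rr)) 0L else
      sum(rr$fail_reason == "out_of_window", na.rm = TRUE),
    short_suffix = if (is.null(rr)) 0L else
      sum(rr$fail_reason == "short_suffix", na.rm = TRUE)
  )
  list(classes = classes, junctions = resolved$junctions, reads = resolved$reads,
       alignment_summary = summary, counters = counters, aln = aln)
}

#' Summary statistics of a detection run
#'
#' @param classes Pair classification table.
#' @param junctions Junction call table (or `NULL`).
#' @param truth Optional list with `truth_pairs` and `truth_junctions` from
#'   [simulate_dataset()]; adds junction recovery metrics.
#' @param config The [resolver_config()] used.
#' @return List: `chimera_rate_pct`, `levels` (level table), `orientation`,
#'   `distance_hist`, `overlap_hist`, `type_counts`, `ratio`
#'   (insertion:pair-end, `NA` when undefined), `recovery` (when truth given).
#' @export
summarize_chimeras <- function(classes, junctions, truth = NULL,
                               config = resolver_config()) {
  n_total <- nrow(classes)
  chim <- classes[!is.na(classes$is_chimera) & classes$is_chimera %in% TRUE, ,
                  drop = FALSE]
  out <- list(
    n_pairs = n_total,
    n_chimeric = nrow(chim),
    chimera_rate_pct = if (n_total > 0) chimera_rate(nrow(chim), n_total) else NA_real_,
    levels = level_proportions(classes),
    orientation = if (!is.null(junctions) && nrow(junctions)) {
      orientation_proportions(junctions)
    } else c(inverted = NA_real_, direct = NA_real_),
    distance_hist = distance_histogram(
      if (is.null(junctions)) data.frame(distance = integer(0)) else junctions,
      max_d = config$window),
    overlap_hist = overlap_histogram(
      if (is.null(junctions)) data.frame(overlap_len = integer(0)) else junctions),
    type_counts = c(
      insertion = sum(chim$chimera_type == "insertion"),
      pair_end = sum(chim$chimera_type == "pair_end"),
      mixed = sum(chim$chimera_type == "mixed"))
  )
  out$ratio <- if (out$type_counts[["pair_end"]] > 0L) {
    out$type_counts[["insertion"]] / out$type_counts[["pair_end"]]
  } else NA_real_
  if (!is.null(truth)) {
    out$recovery <- junction_recovery(junctions, truth$truth_junctions,
                                      truth$truth_pairs, config)
  }
  out
}

# ---- file-based runners -----------------------------------------------------

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_manifest <- function(path, entries, files = character(0)) {
  lines <- c(sprintf("%s\t%s", names(entries), vapply(entries, format, character(1))))
  if (length(files)) {
    lines <- c(lines, sprintf("md5_%s\t%s", basename(files),
                              tools::md5sum(files)))
  }
  writeLines(lines, path)
  path
}

#' Simulate a dataset to files
#'
#' Writes reference FASTA, two FASTQ files, truth TSVs, and a manifest with
#' the config echo and file checksums.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of written file paths, invisibly.
#' @export
run_simulate <- function(config = sim_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(config)
  paths <- c(
    reference = file.path(out_dir, "reference.fasta"),
    fastq1 = file.path(out_dir, "reads_1.fastq"),
    fastq2 = file.path(out_dir, "reads_2.fastq"),
    truth_pairs = file.path(out_dir, "truth_pairs.tsv"),
    truth_junctions = file.path(out_dir, "truth_junctions.tsv")
  )
  write_fasta(sim$reference, paths[["reference"]])
  write_fastq_pairs(sim$pairs, paths[["fastq1"]], paths[["fastq2"]])
  .write_tsv(sim$truth_pairs, paths[["truth_pairs"]])
  tj <- sim$truth_junctions
  if (is.null(tj)) {
    tj <- data.frame(pair_id = character(0), junction_index = integer(0))
  } else {
    tj$former_end_coord <- tj$former_end_coord + 1L       # 1-based on disk
    tj$following_start_coord <- tj$following_start_coord + 1L
  }
  .write_tsv(tj, paths[["truth_junctions"]])
  cfg_flat <- config[!vapply(config, is.null, logical(1))]
  cfg_flat <- lapply(cfg_flat, paste, collapse = ",")
  .write_manifest(file.path(out_dir, "manifest.txt"),
                  c(list(subcommand = "simulate"), cfg_flat), paths)
  invisible(c(paths, manifest = file.path(out_dir, "manifest.txt")))
}

#' Detect chimeras from files
#'
#' @param reference_path Reference FASTA.
#' @param fastq1,fastq2 Paired FASTQ files.
#' @param config A [resolver_config()].
#' @param out_dir Output directory.
#' @return Named character vector of written file paths, invisibly; outputs
#'   are the alignment summary, the junction call table (1-based inclusive
#'   coordinates, one row per junction), and the pair classification table.
#' @export
run_detect <- function(reference_path, fastq1, fastq2,
                       config = resolver_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- read_fasta(reference_path)
  pairs <- read_fastq_pairs(fastq1, fastq2, read_len = config$read_len)
  det <- detect_chimeras(reference, pairs, config)
  paths <- c(
    alignment_summary = file.path(out_dir, "alignment_summary.tsv"),
    junctions = file.path(out_dir, "junctions.tsv"),
    classes = file.path(out_dir, "pair_classes.tsv"),
    counters = file.path(out_dir, "counters.tsv")
  )
  .write_tsv(det$alignment_summary, paths[["alignment_summary"]])
  jx <- det$junctions
  if (is.null(jx)) {
    jx <- data.frame(pair_id = character(0))
  } else {
    for (col in c("former_ref_start", "following_ref_start",
                  "former_end_coord", "following_start_coord")) {
      jx[[col]] <- jx[[col]] + 1L                         # 1-based on disk
    }
    for (col in c("former_read_start", "following_read_start")) {
      jx[[col]] <- jx[[col]] + 1L
    }
  }
  .write_tsv(jx, paths[["junctions"]])
  .write_tsv(det$classes, paths[["classes"]])
  .write_tsv(data.frame(counter = names(det$counters),
                        value = unname(det$counters)), paths[["counters"]])
  .write_manifest(file.path(out_dir, "manifest.txt"),
                  list(subcommand = "detect", reference = reference_path,
                       fastq1 = fastq1, fastq2 = fastq2,
                       seed_len = config$seed_len, window = config$window,
                       min_following_len = config$min_following_len,
                       read_len = config$read_len), paths)
  invisible(c(paths, manifest = file.path(out_dir, "manifest.txt")))
}

#' Compute summary statistics from detection output files
#'
#' @param detect_dir Directory written by [run_detect()].
#' @param truth_dir Optional directory written by [run_simulate()] (adds
#'   recovery metrics).
#' @param config The [resolver_config()] used for detection.
#' @param out_dir Output directory.
#' @return Named character vector of written file paths, invisibly.
#' @export
run_stats <- function(detect_dir, truth_dir = NULL,
                      config = resolver_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rd <- function(p) utils::read.delim(p, stringsAsFactors = FALSE)
  classes <- rd(file.path(detect_dir, "pair_classes.tsv"))
  jx_path <- file.path(detect_dir, "junctions.tsv")
  jx <- rd(jx_path)
  if (nrow(jx)) {
    for (col in c("former_end_coord", "following_start_coord")) {
      jx[[col]] <- jx[[col]] - 1L
    }
    jx$following_read_start <- jx$following_read_start - 1L
  } else jx <- NULL
  truth <- NULL
  if (!is.null(truth_dir)) {
    truth <- list(truth_pairs = rd(file.path(truth_dir, "truth_pairs.tsv")),
                  truth_junctions = rd(file.path(truth_dir, "truth_junctions.tsv")))
    if (nrow(truth$truth_junctions)) {
      truth$truth_junctions$former_end_coord <-
        truth$truth_junctions$former_end_coord - 1L
      truth$truth_junctions$following_start_coord <-
        truth$truth_junctions$following_start_coord - 1L
    }
  }
  s <- summarize_chimeras(classes, jx, truth = truth, config = config)
  report <- c(
    n_pairs = s$n_pairs, n_chimeric = s$n_chimeric,
    chimera_rate_pct = s$chimera_rate_pct,
    inverted_fraction = unname(s$orientation["inverted"]),
    distance_mode_nt = histogram_mode(s$distance_hist),
    overlap_mode_nt = histogram_mode(s$overlap_hist),
    n_insertion = unname(s$type_counts["insertion"]),
    n_pair_end = unname(s$type_counts["pair_end"]),
    n_mixed = unname(s$type_counts["mixed"]),
    insertion_pairend_ratio = s$ratio
  )
  if (!is.null(s$recovery)) {
    report <- c(report,
                junction_sensitivity = s$recovery$sensitivity,
                junction_exactness = s$recovery$exactness,
                n_eligible_junctions = s$recovery$n_eligible)
  }
  paths <- c(
    report = file.path(out_dir, "report.tsv"),
    levels = file.path(out_dir, "level_table.tsv"),
    distance_hist = file.path(out_dir, "distance_histogram.tsv"),
    overlap_hist = file.path(out_dir, "overlap_histogram.tsv")
  )
  .write_tsv(data.frame(metric = names(report), value = unname(report)),
             paths[["report"]])
  .write_tsv(s$levels, paths[["levels"]])
  .write_tsv(data.frame(bin = s$distance_hist$bin_edges,
                        count = s$distance_hist$counts), paths[["distance_hist"]])
  .write_tsv(data.frame(bin = s$overlap_hist$bin_edges,
                        count = s$overlap_hist$counts), paths[["overlap_hist"]])
  .write_manifest(file.path(out_dir, "manifest.txt"),
                  list(subcommand = "stats", detect_dir = detect_dir,
                       truth_dir = if (is.null(truth_dir)) "" else truth_dir),
                  paths)
  invisible(c(paths, manifest = file.path(out_dir, "manifest.txt")))
}
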
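# Pair-level chimera taxonomy: combine per-read junction resolutions with
# pair mapping geometry into (level 1/2/3, insertion / pair-end / mixed).

#' Detect a discordant insert (insertion chimera geometry)
#'
#' For a pair whose reads are both full-length mapped individually, flags the
#' pair when the mapping geometry violates paired-end concordance: different
#' chromosomes, same strand, reversed order, or inner distance outside the
#' concordance range. Such pairs carry one inferred chimeric junction inside
#' the unsequenced insert.
#'
#' @param p1,p2 Single placements for read1/read2: lists or one-row data
#'   frames with `chrom`, `pos` (0-based window start), `strand`.
#' @param read_len Read length (nt).
#' @param concordance_range Length-2 numeric inner-distance interval.
#' @return List with `flag` (TRUE when discordant) and `reason` (`"concordant"`,
#'   `"different_chrom"`, `"same_strand"`, `"reversed_order"`,
#'   `"inner_distance"`).
#' @export
detect_insert_discordance <- function(p1, p2, read_len,
                                      concordance_range = c(180, 420)) {
  if (is.null(p1) || is.null(p2) || is.na(p1$chrom) || is.na(p2$chrom)) {
    stop("both reads must be full-length mapped to judge insert geometry",
         call. = FALSE)
  }
  if (p1$chrom != p2$chrom) return(list(flag = TRUE, reason = "different_chrom"))
  if (p1$strand == p2$strand) return(list(flag = TRUE, reason = "same_strand"))
  fs <- if (p1$strand == "+") p1$pos else p2$pos
  rs <- if (p1$strand == "+") p2$pos else p1$pos
  if (fs >= rs + read_len) return(list(flag = TRUE, reason = "reversed_order"))
  inner <- rs - (fs + read_len)
  if (inner < concordance_range[1] || inner > concordance_range[2]) {
    return(list(flag = TRUE, reason = "inner_distance"))
  }
  list(flag = FALSE, reason = "concordant")
}

#' Classify one read pair
#'
#' Level is the number of chimeric events: visible junctions on either read
#' plus the single inferable insert junction, capped at 3 (deeper chimeras are
#' reported as 3-level). Type is `insertion` when the only event is the
#' inferred insert junction, `pair_end` when all events are visible read
#' junctions, and `mixed` otherwise.
#'
#' @param n_read1_junctions,n_read2_junctions Visible junction counts.
#' @param insert_flag TRUE when the pair geometry implies an insert junction.
#' @param resolution `"ok"` or `"ambiguous"`; ambiguous pairs are excluded
#'   from chimera accounting and reported separately.
#' @return List with `is_chimera`, `level` (NA for non-chimeras/ambiguous),
#'   `chimera_type` (`insertion`/`pair_end`/`mixed`/NA), junction counts,
#'   `insert_flag`, and `resolution`.
#' @export
classify_pair <- function(n_read1_junctions, n_read2_junctions, insert_flag,
                          resolution = "ok") {
  n_vis <- n_read1_junctions + n_read2_junctions
  if (resolution == "ambiguous") {
    return(list(is_chimera = NA, level = NA_integer_,
                chimera_type = NA_character_,
                n_read1_junctions = n_read1_junctions,
                n_read2_junctions = n_read2_junctions,
                insert_flag = insert_flag, resolution = "ambiguous"))
  }
  n_events <- n_vis + as.integer(insert_flag)
  if (n_events == 0L) {
    return(list(is_chimera = FALSE, level = NA_integer_,
                chimera_type = NA_character_,
                n_read1_junctions = n_read1_junctions,
                n_read2_junctions = n_read2_junctions,
                insert_flag = insert_flag, resolution = "ok"))
  }
  type <- if (n_vis == 0L) "insertion"
          else if (!insert_flag) "pair_end"
          else "mixed"
  list(is_chimera = TRUE, level = min(n_events, 3L), chimera_type = type,
       n_read1_junctions = n_read1_junctions,
       n_read2_junctions = n_read2_junctions,
       insert_flag = insert_flag, resolution = "ok")
}

#' Classify every pair of a dataset
#'
#' Joins alignment statuses with per-read resolutions. Pairs with both reads
#' full-length mapped get the insert-geometry check; pairs with any ambiguous
#' read resolution are set aside as ambiguous.
#'
#' @param aln A `pair_alignment` from [align_dataset()].
#' @param resolved Output of [resolve_candidates()].
#' @return `data.frame` with one row per pair: `pair_id`, `is_chimera`,
#'   `level`, `chimera_type`, `n_read1_junctions`, `n_read2_junctions`,
#'   `insert_flag`, `resolution`.
#' @export
classify_dataset <- function(aln, resolved) {
  st <- aln$status
  cfg <- aln$config
  rr <- resolved$reads
  n1 <- integer(nrow(st)); n2 <- integer(nrow(st))
  ambig <- logical(nrow(st))
  if (nrow(rr)) {
    key1 <- rr$pair_id[rr$read_end == 1L]
    key2 <- rr$pair_id[rr$read_end == 2L]
    m1 <- match(st$pair_id, key1)
    m2 <- match(st$pair_id, key2)
    r1 <- rr[rr$read_end == 1L, , drop = FALSE]
    r2 <- rr[rr$read_end == 2L, , drop = FALSE]
    n1 <- ifelse(is.na(m1), 0L, r1$n_junctions[m1])
    n2 <- ifelse(is.na(m2), 0L, r2$n_junctions[m2])
    ambig <- (!is.na(m1) & r1$status[m1] == "ambiguous") |
             (!is.na(m2) & r2$status[m2] == "ambiguous")
  }
  out <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    insert_flag <- FALSE
    if (st$full_status[i] %in% c("PE_mapped", "SE_mapped_both") &&
        st$r1_n_full[i] > 0L && st$r2_n_full[i] > 0L) {
      d <- detect_insert_discordance(
        list(chrom = st$r1_chrom[i], pos = st$r1_start[i], strand = st$r1_strand[i]),
        list(chrom = st$r2_chrom[i], pos = st$r2_start[i], strand = st$r2_strand[i]),
        read_len = cfg$read_len, concordance_range = cfg$concordance_range)
      insert_flag <- d$flag
    }
    cl <- classify_pair(n1[i], n2[i], insert_flag,
                        resolution = if (ambig[i]) "ambiguous" else "ok")
    out[[i]] <- data.frame(pair_id = st$pair_id[i],
                           is_chimera = cl$is_chimera, level = cl$level,
                           chimera_type = if (is.null(cl$chimera_type)) NA_character_ else cl$chimera_type,
                           n_read1_junctions = cl$n_read1_junctions,
                           n_read2_junctions = cl$n_read2_junctions,
                           insert_flag = cl$insert_flag,
                           resolution = cl$resolution,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
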
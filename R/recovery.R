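# Recovery metrics against simulator ground truth.

#' Junction recovery against ground truth
#'
#' Compares detected junction calls with the simulator's observation-frame
#' truth. A truth junction is *eligible* for detection when the whole junction
#' chain of its observing read is resolvable under the configured anchors: the
#' anchor seed avoids the first junction (read offset >= `seed_len`), every
#' subsequent subsection provides at least `min_following_len` bases before
#' the next junction, and the final suffix is at least `min_following_len` nt.
#' Junctions violating these bounds are documented detection misses, not
#' errors.
#'
#' A truth junction counts as detected when a junction was called in the same
#' read at the same read offset; a detected junction is *exact* when its
#' former-end coordinate, following-start coordinate, signed distance and
#' overlap length all equal the truth values.
#'
#' @param detected Junction table from [resolve_candidates()] (may be `NULL`).
#' @param truth_junctions,truth_pairs Truth tables from [simulate_dataset()].
#' @param config The [resolver_config()] used for detection.
#' @return List: `n_eligible`, `n_detected`, `sensitivity`, `n_calls`,
#'   `n_exact`, `exactness`, and `per_junction` (truth junctions annotated
#'   with `eligible`, `detected`, `exact`).
#' @export
junction_recovery <- function(detected, truth_junctions, truth_pairs,
                              config = resolver_config()) {
  tj <- truth_junctions[truth_junctions$obs_frame %in% c("read1", "read2"), ,
                        drop = FALSE]
  fl <- truth_pairs$fragment_len[match(tj$pair_id, truth_pairs$pair_id)]
  off <- ifelse(tj$obs_frame == "read1", tj$frag_offset, fl - tj$frag_offset)
  read_end <- ifelse(tj$obs_frame == "read1", 1L, 2L)

  # Eligibility is a property of the whole junction chain within a read: the
  # resolver reaches junction i only after placing every earlier subsection,
  # each of which needs >= min_following_len bases before the next junction.
  rid <- paste(tj$pair_id, read_end)
  eligible <- logical(nrow(tj))
  for (g in split(seq_len(nrow(tj)), rid)) {
    o <- sort(off[g])
    ok <- o[1] >= config$seed_len &&
      all(diff(o) >= config$min_following_len) &&
      (config$read_len - o[length(o)]) >= config$min_following_len
    eligible[g] <- ok
  }

  det_key <- exact_key <- character(0)
  if (!is.null(detected) && nrow(detected)) {
    det_key <- paste(detected$pair_id, detected$read_end,
                     detected$following_read_start)
    exact_key <- paste(detected$pair_id, detected$read_end,
                       detected$following_read_start,
                       detected$former_end_coord,
                       detected$following_start_coord,
                       detected$distance, detected$overlap_len)
  }
  t_key <- paste(tj$pair_id, read_end, off)
  t_exact <- paste(tj$pair_id, read_end, off, tj$former_end_coord,
                   tj$following_start_coord, tj$distance, tj$realized_overlap)
  det <- t_key %in% det_key
  n_calls <- length(det_key)
  n_exact <- sum(exact_key %in% t_exact)

  per <- cbind(tj, data.frame(read_end = read_end, read_offset = off,
                              eligible = eligible, detected = det,
                              exact = t_exact %in% exact_key))
  list(
    n_eligible = sum(eligible),
    n_detected = sum(det & eligible),
    sensitivity = if (sum(eligible)) sum(det & eligible) / sum(eligible) else NA_real_,
    n_calls = n_calls,
    n_exact = n_exact,
    exactness = if (n_calls) n_exact / n_calls else NA_real_,
    per_junction = per
  )
}
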
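# Subsection alignment: resolve a candidate read into exact-match segments and
# call the junctions between them.
#
# The procedure per read: extend the anchored seed base by base until the
# first mismatch (the "former" subsection), relocate the unplaced suffix by
# exact probe search in a +/- `window` bp region around the former
# subsection's end coordinate on both strands (the "following" subsection),
# then reverse-extend from the following subsection's start to measure the
# microhomology (overlap) shared with the former subsection's tail. Repeat
# with the following subsection as the new former until the read is consumed.
#
# Coordinates: read and reference intervals are 0-based half-open internally.
# A segment on strand "-" means the read bases equal the reverse complement
# of the forward-strand reference window.

.segment <- function(read_start, read_end, chrom, ref_start, ref_end, strand) {
  list(read_start = as.integer(read_start), read_end = as.integer(read_end),
       chrom = chrom, ref_start = as.integer(ref_start),
       ref_end = as.integer(ref_end), strand = strand)
}

#' Extend an anchored match base by base until the first mismatch
#'
#' The anchor of length `anchor_len` starting at `read_offset` on the read
#' must already match the oriented reference at (`chrom`, `ref_pos`,
#' `strand`), where `ref_pos` is the forward-strand left end of the anchor
#' window. Extension proceeds rightward along the read (leftward on the
#' forward strand for `"-"` placements).
#'
#' @param read Read sequence.
#' @param read_offset 0-based read position of the anchor start.
#' @param chrom,ref_pos,strand Anchor placement.
#' @param reference Named character vector or `chimera_ref` handle.
#' @param anchor_len Anchor length in nt (default 30).
#' @return The smallest read offset `e` such that `read[read_offset, e)` is
#'   the maximal contiguous exact match; `e` equals the read length when the
#'   whole remainder matches.
#' @export
extend_match <- function(read, read_offset, chrom, ref_pos, strand, reference,
                         anchor_len = 30L) {
  refh <- .ref_handle(reference)
  L <- nchar(read)
  read_offset <- as.integer(read_offset); ref_pos <- as.integer(ref_pos)
  avail_read <- L - read_offset
  avail_ref <- if (strand == "+") refh$len[[chrom]] - ref_pos
               else ref_pos + anchor_len
  avail <- min(avail_read, avail_ref)
  rr <- charToRaw(substr(read, read_offset + 1L, read_offset + avail))
  ref_slice <- if (strand == "+") {
    .ref_raw(refh, chrom, ref_pos, ref_pos + avail)
  } else {
    .ref_raw_oriented(refh, chrom, ref_pos + anchor_len - avail,
                      ref_pos + anchor_len, "-")
  }
  run <- .match_run(rr, ref_slice)
  if (run < min(anchor_len, avail_read)) {
    stop(sprintf("anchor does not match the reference at %s:%d(%s)",
                 chrom, ref_pos, strand), call. = FALSE)
  }
  read_offset + run
}

# Segment produced by extending an anchor (window [ref_pos, ref_pos+anchor_len)
# forward-strand) from read_offset to extended end e.
.extended_segment <- function(read_offset, e, chrom, ref_pos, strand, anchor_len) {
  len <- e - read_offset
  if (strand == "+") {
    .segment(read_offset, e, chrom, ref_pos, ref_pos + len, "+")
  } else {
    .segment(read_offset, e, chrom, ref_pos + anchor_len - len,
             ref_pos + anchor_len, "-")
  }
}

# Forward-strand coordinate of the template base matching the segment's last
# read base ("end coordinate of the former subsection").
.coord_end <- function(seg) {
  if (seg$strand == "+") seg$ref_end - 1L else seg$ref_start
}
# Coordinate of the template base matching the segment's first read base.
.coord_start <- function(seg) {
  if (seg$strand == "+") seg$ref_start else seg$ref_end - 1L
}

#' Signed chimeric distance between adjacent subsections
#'
#' `D = C_former,end - C_following,start` on forward-strand coordinates of the
#' matched template bases. Cross-chromosome junctions have no distance (`NA`).
#'
#' @param former,following Segments (as produced by the resolver).
#' @return Signed integer distance, or `NA` across chromosomes.
#' @export
chimeric_distance <- function(former, following) {
  if (!identical(former$chrom, following$chrom)) return(NA_integer_)
  .coord_end(former) - .coord_start(following)
}

#' Junction orientation
#'
#' Inverted when the two subsections align to opposite strands, direct when
#' they share a strand.
#'
#' @param former,following Segments, or anything with a `strand` field.
#' @return `"inverted"` or `"direct"`.
#' @export
junction_orientation <- function(former, following) {
  if (former$strand == following$strand) "direct" else "inverted"
}

#' Overlap (microhomology) length at a junction
#'
#' Reverse extension from the following subsection's start: the maximal `L`
#' such that the `L` oriented reference bases immediately preceding the
#' following subsection's first matched base (in its reading direction) equal
#' the last `L` read bases of the former subsection. Capped at the former
#' subsection's length and the available reference.
#'
#' @param former,following Segments of the junction.
#' @param reference Named character vector or `chimera_ref` handle.
#' @return Overlap length in nt (>= 0).
#' @export
compute_overlap <- function(former, following, reference) {
  refh <- .ref_handle(reference)
  former_len <- former$read_end - former$read_start
  if (following$strand == "+") {
    room <- following$ref_start
    maxL <- min(former_len, room)
    preceding <- .ref_raw(refh, following$chrom,
                          following$ref_start - maxL, following$ref_start)
  } else {
    room <- refh$len[[following$chrom]] - following$ref_end
    maxL <- min(former_len, room)
    preceding <- .ref_raw_oriented(refh, following$chrom, following$ref_end,
                                   following$ref_end + maxL, "-")
  }
  if (maxL <= 0L) return(0L)
  tail_bases <- .ref_raw_oriented(refh, former$chrom, former$ref_start,
                                  former$ref_end, former$strand)
  tail_bases <- tail_bases[(length(tail_bases) - maxL + 1L):length(tail_bases)]
  .match_run(rev(tail_bases), rev(preceding))
}

#' Locate the following subsection of an unplaced suffix
#'
#' Searches both strands of the `+/- config$window` bp region around the
#' former subsection's end coordinate for exact placements of a probe (the
#' first `config$min_following_len` bases of the suffix), extends each
#' placement rightward on the read, and returns the placement with the
#' longest extension. Ties break to the smallest `|D|`, then `+` strand
#' before `-`; a tie surviving both rules is ambiguous. The search is
#' intra-chromosomal, so `|D| <= window` for every placement by construction.
#'
#' @param read Read sequence.
#' @param suffix_start 0-based read offset where the unplaced suffix begins.
#' @param anchor The former segment.
#' @param reference Named character vector or `chimera_ref` handle.
#' @param config A [resolver_config()].
#' @return List with `status` (`"ok"`, `"none"`, `"ambiguous"`); for `"ok"`,
#'   `segment` (the extended following segment) and `distance` (signed D);
#'   for `"none"`, `reason` (`"short_suffix"` or `"out_of_window"`).
#' @export
locate_following <- function(read, suffix_start, anchor, reference, config) {
  refh <- .ref_handle(reference)
  L <- nchar(read)
  plen <- config$min_following_len
  if (L - suffix_start < plen) {
    return(list(status = "none", reason = "short_suffix"))
  }
  probe <- substr(read, suffix_start + 1L, suffix_start + plen)
  chrom <- anchor$chrom
  clen <- refh$len[[chrom]]
  cfe <- .coord_end(anchor)
  W <- config$window

  find_starts <- function(pattern, lo, hi) {
    # forward-strand match starts of `pattern` with start coordinate in [lo, hi]
    lo <- max(lo, 0L); hi <- min(hi, clen - plen)
    if (hi < lo) return(integer(0))
    region <- substr(refh$seq[[chrom]], lo + 1L, min(clen, hi + plen))
    m <- gregexpr(pattern, region, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(integer(0))
    as.integer(lo + m - 1L)
  }

  cands <- list()
  # plus strand: probe's first base at coordinate q = match start
  for (q in find_starts(probe, cfe - W, cfe + W)) {
    cands[[length(cands) + 1L]] <- list(q = q, s0 = q, strand = "+")
  }
  # minus strand: probe's first base at coordinate q = match end of revcomp(probe)
  for (s0 in find_starts(revcomp(probe), cfe - W - plen + 1L, cfe + W - plen + 1L)) {
    q <- s0 + plen - 1L
    if (q >= cfe - W && q <= cfe + W) {
      cands[[length(cands) + 1L]] <- list(q = q, s0 = s0, strand = "-")
    }
  }
  if (!length(cands)) return(list(status = "none", reason = "out_of_window"))

  scored <- lapply(cands, function(cd) {
    e <- extend_match(read, suffix_start, chrom, cd$s0, cd$strand, refh,
                      anchor_len = plen)
    seg <- .extended_segment(suffix_start, e, chrom, cd$s0, cd$strand, plen)
    list(segment = seg, distance = cfe - cd$q, ext = e - suffix_start,
         strand = cd$strand)
  })
  ext <- vapply(scored, `[[`, numeric(1), "ext")
  scored <- scored[ext == max(ext)]
  if (length(scored) > 1L) {
    ad <- abs(vapply(scored, `[[`, numeric(1), "distance"))
    scored <- scored[ad == min(ad)]
  }
  if (length(scored) > 1L) {
    strands <- vapply(scored, `[[`, character(1), "strand")
    if (any(strands == "+") && any(strands == "-")) {
      scored <- scored[strands == "+"]
    }
  }
  if (length(scored) > 1L) return(list(status = "ambiguous"))
  list(status = "ok", segment = scored[[1]]$segment,
       distance = as.integer(scored[[1]]$distance))
}

#' Resolve a candidate read into segments and junctions
#'
#' Repeats extend -> locate -> overlap, treating each placed following
#' subsection as the new former, until the read is consumed, the junction cap
#' is reached, or relocation fails.
#'
#' @param read Read sequence.
#' @param anchor List or one-row data.frame with the anchoring seed hit:
#'   `chrom`, `ref_start` (0-based forward left end of the seed window),
#'   `strand`. The seed offset on the read is 0.
#' @param reference Named character vector or `chimera_ref` handle.
#' @param config A [resolver_config()].
#' @return A `resolved_read` list: `segments` (data.frame, one row per
#'   segment, read/ref intervals 0-based half-open), `junctions` (data.frame:
#'   `junction_index`, former/following coordinates and strands,
#'   `overlap_len`, `distance`, `abs_distance`, `orientation`), `status`
#'   (`full`, `partial`, `ambiguous`, `not_chimeric`),
#'   `unplaced_suffix_len`, and `fail_reason` (for partial resolutions).
#' @export
resolve_read <- function(read, anchor, reference, config = resolver_config()) {
  refh <- .ref_handle(reference)
  L <- nchar(read)
  e0 <- extend_match(read, 0L, anchor$chrom, anchor$ref_start, anchor$strand,
                     refh, anchor_len = config$seed_len)
  seg <- .extended_segment(0L, e0, anchor$chrom, anchor$ref_start,
                           anchor$strand, config$seed_len)
  segments <- list()
  junctions <- list()
  status <- NULL
  fail_reason <- NA_character_
  repeat {
    segments[[length(segments) + 1L]] <- seg
    e <- seg$read_end
    if (e == L) {
      status <- if (length(junctions)) "full" else "not_chimeric"
      break
    }
    if (length(junctions) >= config$max_junctions) {
      status <- "partial"; fail_reason <- "max_junctions"
      break
    }
    loc <- locate_following(read, e, seg, refh, config)
    if (loc$status == "none") {
      status <- "partial"; fail_reason <- loc$reason
      break
    }
    if (loc$status == "ambiguous") {
      status <- "ambiguous"
      break
    }
    jx <- list(
      former = seg, following = loc$segment,
      overlap_len = compute_overlap(seg, loc$segment, refh),
      distance = loc$distance,
      orientation = junction_orientation(seg, loc$segment)
    )
    junctions[[length(junctions) + 1L]] <- jx
    seg <- loc$segment
  }
  seg_df <- do.call(rbind, lapply(segments, function(s)
    data.frame(read_start = s$read_start, read_end = s$read_end,
               chrom = s$chrom, ref_start = s$ref_start, ref_end = s$ref_end,
               strand = s$strand, stringsAsFactors = FALSE)))
  jx_df <- if (length(junctions)) {
    do.call(rbind, lapply(seq_along(junctions), function(i) {
      j <- junctions[[i]]
      data.frame(
        junction_index = i,
        chrom = j$former$chrom,
        former_read_start = j$former$read_start,
        former_read_end = j$former$read_end,
        former_ref_start = j$former$ref_start,
        former_ref_end = j$former$ref_end,
        former_strand = j$former$strand,
        following_read_start = j$following$read_start,
        following_read_end = j$following$read_end,
        following_ref_start = j$following$ref_start,
        following_ref_end = j$following$ref_end,
        following_strand = j$following$strand,
        former_end_coord = .coord_end(j$former),
        following_start_coord = .coord_start(j$following),
        overlap_len = j$overlap_len,
        distance = j$distance,
        abs_distance = abs(j$distance),
        orientation = j$orientation,
        stringsAsFactors = FALSE
      )
    }))
  } else {
    data.frame(junction_index = integer(0), chrom = character(0),
               former_read_start = integer(0), former_read_end = integer(0),
               former_ref_start = integer(0), former_ref_end = integer(0),
               former_strand = character(0),
               following_read_start = integer(0), following_read_end = integer(0),
               following_ref_start = integer(0), following_ref_end = integer(0),
               following_strand = character(0),
               former_end_coord = integer(0), following_start_coord = integer(0),
               overlap_len = integer(0), distance = integer(0),
               abs_distance = integer(0), orientation = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(segments = seg_df, junctions = jx_df, status = status,
                 unplaced_suffix_len = L - segments[[length(segments)]]$read_end,
                 fail_reason = fail_reason),
            class = "resolved_read")
}

#' Resolve every candidate read of a dataset
#'
#' @param candidates Candidate table from [select_candidates()].
#' @param reference Named character vector or `chimera_ref` handle.
#' @param config A [resolver_config()].
#' @return List with `reads` (data.frame: `pair_id`, `read_end`, `status`,
#'   `n_junctions`, `unplaced_suffix_len`, `fail_reason`) and `junctions`
#'   (row-bound junction tables with `pair_id`/`read_end` prepended).
#' @export
resolve_candidates <- function(candidates, reference, config = resolver_config()) {
  refh <- .ref_handle(reference)
  n <- nrow(candidates)
  reads <- data.frame(pair_id = character(n), read_end = integer(n),
                      status = character(n), n_junctions = integer(n),
                      unplaced_suffix_len = integer(n),
                      fail_reason = character(n), stringsAsFactors = FALSE)
  jx <- vector("list", n)
  for (i in seq_len(n)) {
    res <- resolve_read(candidates$seq[i],
                        list(chrom = candidates$chrom[i],
                             ref_start = candidates$ref_start[i],
                             strand = candidates$strand[i]),
                        refh, config)
    reads$pair_id[i] <- candidates$pair_id[i]
    reads$read_end[i] <- candidates$read_end[i]
    reads$status[i] <- res$status
    reads$n_junctions[i] <- nrow(res$junctions)
    reads$unplaced_suffix_len[i] <- res$unplaced_suffix_len
    reads$fail_reason[i] <- res$fail_reason
    if (nrow(res$junctions)) {
      jx[[i]] <- cbind(data.frame(pair_id = candidates$pair_id[i],
                                  read_end = candidates$read_end[i],
                                  stringsAsFactors = FALSE),
                       res$junctions)
    }
  }
  jx <- jx[!vapply(jx, is.null, logical(1))]
  junctions <- if (length(jx)) do.call(rbind, jx) else NULL
  list(reads = reads, junctions = junctions)
}
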
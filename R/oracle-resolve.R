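# Exhaustive brute-force twin of the resolver, for property-based equivalence
# testing on small references. No code shared with the production path: all
# matching is done by naive substring comparison on character strings, and the
# tie policy (longest extension, then smallest |D|, then '+' strand, else
# ambiguous) is re-stated here from scratch.

.naive_revcomp <- function(s) {
  paste0(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# 0-based start positions of exact occurrences of `pattern` in `seq`
.naive_find <- function(seq, pattern) {
  n <- nchar(seq); m <- nchar(pattern)
  if (m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  which(substring(seq, starts, starts + m - 1L) == pattern) - 1L
}

# naive rightward extension: read offset ro anchored so that read position
# ro + j faces forward coordinate ref_pos + anchor_len - 1 - j ("-") or
# ref_pos + j ("+"); returns exclusive read end of the maximal match
.naive_extend <- function(read, ro, seq, ref_pos, strand, anchor_len) {
  L <- nchar(read); n <- nchar(seq)
  comp <- function(ch) chartr("ACGTN", "TGCAN", ch)
  e <- ro
  while (e < L) {
    j <- e - ro
    coord <- if (strand == "+") ref_pos + j else ref_pos + anchor_len - 1L - j
    if (coord < 0L || coord >= n) break
    rb <- substr(read, e + 1L, e + 1L)
    gb <- substr(seq, coord + 1L, coord + 1L)
    if (strand == "-") gb <- comp(gb)
    if (rb != gb) break
    e <- e + 1L
  }
  e
}

.naive_segment <- function(ro, e, chrom, ref_pos, strand, anchor_len) {
  len <- e - ro
  if (strand == "+") {
    list(read_start = ro, read_end = e, chrom = chrom, ref_start = ref_pos,
         ref_end = ref_pos + len, strand = "+")
  } else {
    list(read_start = ro, read_end = e, chrom = chrom,
         ref_start = ref_pos + anchor_len - len,
         ref_end = ref_pos + anchor_len, strand = "-")
  }
}

#' Exhaustive resolver oracle
#'
#' Resolves a candidate read by enumerating every exact placement of each
#' unplaced suffix with naive substring search over the whole chromosome,
#' filtering placements to the search window, and applying the same tie policy
#' as [resolve_read()]. Intended for references of a few kb.
#'
#' @param read Read sequence.
#' @param anchor Anchoring seed hit (`chrom`, `ref_start`, `strand`); when
#'   `NULL`, derived as the unique placement of the read's seed (an error if
#'   not unique).
#' @param reference Named character vector.
#' @param config A [resolver_config()].
#' @return Same structure as [resolve_read()].
#' @export
oracle_resolve <- function(read, anchor = NULL, reference,
                           config = resolver_config()) {
  k <- config$seed_len
  if (is.null(anchor)) {
    seed <- substr(read, 1L, k)
    hits <- list()
    for (ch in names(reference)) {
      for (p in .naive_find(reference[[ch]], seed)) {
        hits[[length(hits) + 1L]] <- list(chrom = ch, ref_start = p, strand = "+")
      }
      for (p in .naive_find(reference[[ch]], .naive_revcomp(seed))) {
        hits[[length(hits) + 1L]] <- list(chrom = ch, ref_start = p, strand = "-")
      }
    }
    if (length(hits) != 1L) {
      stop(sprintf("seed has %d placements; oracle needs a unique anchor",
                   length(hits)), call. = FALSE)
    }
    anchor <- hits[[1]]
  }
  L <- nchar(read)
  W <- config$window
  plen <- config$min_following_len
  seq <- reference[[anchor$chrom]]

  coord_end <- function(s) if (s$strand == "+") s$ref_end - 1L else s$ref_start
  coord_start <- function(s) if (s$strand == "+") s$ref_start else s$ref_end - 1L

  e0 <- .naive_extend(read, 0L, seq, anchor$ref_start, anchor$strand, k)
  if (e0 < k) stop("anchor does not match the reference", call. = FALSE)
  seg <- .naive_segment(0L, e0, anchor$chrom, anchor$ref_start, anchor$strand, k)

  segments <- list(); junctions <- list()
  status <- NULL; fail_reason <- NA_character_
  repeat {
    segments[[length(segments) + 1L]] <- seg
    e <- seg$read_end
    if (e == L) { status <- if (length(junctions)) "full" else "not_chimeric"; break }
    if (length(junctions) >= config$max_junctions) {
      status <- "partial"; fail_reason <- "max_junctions"; break
    }
    if (L - e < plen) { status <- "partial"; fail_reason <- "short_suffix"; break }
    probe <- substr(read, e + 1L, e + plen)
    cfe <- coord_end(seg)
    cands <- list()
    for (s0 in .naive_find(seq, probe)) {
      if (s0 >= cfe - W && s0 <= cfe + W) {
        cands[[length(cands) + 1L]] <- list(q = s0, s0 = s0, strand = "+")
      }
    }
    for (s0 in .naive_find(seq, .naive_revcomp(probe))) {
      q <- s0 + plen - 1L
      if (q >= cfe - W && q <= cfe + W) {
        cands[[length(cands) + 1L]] <- list(q = q, s0 = s0, strand = "-")
      }
    }
    if (!length(cands)) { status <- "partial"; fail_reason <- "out_of_window"; break }
    scored <- lapply(cands, function(cd) {
      e2 <- .naive_extend(read, e, seq, cd$s0, cd$strand, plen)
      list(seg = .naive_segment(e, e2, anchor$chrom, cd$s0, cd$strand, plen),
           D = cfe - cd$q, ext = e2 - e, strand = cd$strand)
    })
    ext <- vapply(scored, `[[`, numeric(1), "ext")
    scored <- scored[ext == max(ext)]
    if (length(scored) > 1L) {
      ad <- abs(vapply(scored, `[[`, numeric(1), "D"))
      scored <- scored[ad == min(ad)]
    }
    if (length(scored) > 1L) {
      strands <- vapply(scored, `[[`, character(1), "strand")
      if (any(strands == "+") && any(strands == "-")) scored <- scored[strands == "+"]
    }
    if (length(scored) > 1L) { status <- "ambiguous"; break }
    nxt <- scored[[1]]$seg
    junctions[[length(junctions) + 1L]] <- list(
      former = seg, following = nxt,
      overlap_len = oracle_overlap(reference, seg, nxt),
      distance = as.integer(scored[[1]]$D),
      orientation = if (seg$strand == nxt$strand) "direct" else "inverted"
    )
    seg <- nxt
  }
  seg_df <- do.call(rbind, lapply(segments, function(s)
    data.frame(read_start = s$read_start, read_end = s$read_end, chrom = s$chrom,
               ref_start = s$ref_start, ref_end = s$ref_end, strand = s$strand,
               stringsAsFactors = FALSE)))
  jx_df <- if (length(junctions)) {
    do.call(rbind, lapply(seq_along(junctions), function(i) {
      j <- junctions[[i]]
      data.frame(
        junction_index = i, chrom = j$former$chrom,
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
        former_end_coord = coord_end(j$former),
        following_start_coord = coord_start(j$following),
        overlap_len = j$overlap_len, distance = j$distance,
        abs_distance = abs(j$distance), orientation = j$orientation,
        stringsAsFactors = FALSE
      )
    }))
  } else NULL
  list(segments = seg_df, junctions = jx_df, status = status,
       unplaced_suffix_len = L - segments[[length(segments)]]$read_end,
       fail_reason = fail_reason)
}
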
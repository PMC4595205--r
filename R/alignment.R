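# Two alignment passes over a read-pair dataset: full-length placement of each
# read and placement of its 30-nt anchor seed; pair-level concordance; and
# selection of candidate chimeric reads (seed maps, full read does not).

# Full-length exact placements of one read: data.frame(chrom, pos, strand)
# where pos is the 0-based forward-strand left end of the read-length window.
.full_placements <- function(refh, index, read) {
  L <- nchar(read)
  k <- index$k
  out <- list()
  # plus strand: anchor on the read's prefix k-mer, then verify the window
  fwd <- .lookup_fwd(index, substr(read, 1L, k))
  if (nrow(fwd)) {
    keep <- vapply(seq_len(nrow(fwd)), function(i) {
      ch <- fwd$chrom[i]; p <- fwd$pos[i]
      p + L <= refh$len[[ch]] &&
        substr(refh$seq[[ch]], p + 1L, p + L) == read
    }, logical(1))
    f <- fwd[keep, ]
    if (nrow(f)) out[["+"]] <- data.frame(chrom = f$chrom, pos = f$pos,
                                          strand = "+", stringsAsFactors = FALSE)
  }
  # minus strand: plus placements of the reverse complement
  rc <- revcomp(read)
  bwd <- .lookup_fwd(index, substr(rc, 1L, k))
  if (nrow(bwd)) {
    keep <- vapply(seq_len(nrow(bwd)), function(i) {
      ch <- bwd$chrom[i]; p <- bwd$pos[i]
      p + L <= refh$len[[ch]] &&
        substr(refh$seq[[ch]], p + 1L, p + L) == rc
    }, logical(1))
    b <- bwd[keep, ]
    if (nrow(b)) out[["-"]] <- data.frame(chrom = b$chrom, pos = b$pos,
                                          strand = "-", stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$pos, res$strand), , drop = FALSE]
}

# Best concordant geometry between two placement sets, or NULL.
# Concordance: same chrom, opposite strands, the plus-strand read upstream of
# the minus-strand read's end, inner distance (gap between windows) in range.
.pe_concordant <- function(p1, p2, read_len, concordance_range) {
  if (!nrow(p1) || !nrow(p2)) return(NULL)
  for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
    if (p1$chrom[i] != p2$chrom[j]) next
    if (p1$strand[i] == p2$strand[j]) next
    if (p1$strand[i] == "+") { fs <- p1$pos[i]; rs <- p2$pos[j] }
    else { fs <- p2$pos[j]; rs <- p1$pos[i] }
    if (fs >= rs + read_len) next          # forward read must start before reverse read ends
    inner <- rs - (fs + read_len)
    if (inner >= concordance_range[1] && inner <= concordance_range[2]) {
      return(list(chrom = p1$chrom[i], inner = inner,
                  fwd_start = fs, rev_start = rs))
    }
  }
  NULL
}

#' Full-length paired-end mapping status of one pair
#'
#' Emulates a paired-end mapper's verdict under an exact-match contract: a
#' read is full-length mapped iff its entire length has an exact placement;
#' the pair is `PE_mapped` iff some placement combination is concordant
#' (opposite strands, proper order, inner distance within
#' `config$concordance_range` on one chromosome).
#'
#' @param reference Named character vector (or `chimera_ref` handle).
#' @param index `reference_index` built with `k = config$seed_len`.
#' @param pair One-row read-pair `data.frame`.
#' @param config A [resolver_config()].
#' @return List with `full_status` (one of `PE_mapped`, `SE_mapped_read1`,
#'   `SE_mapped_read2`, `SE_mapped_both`, `unmapped`), per-read placement
#'   tables `read1`, `read2`, and `geometry` (for concordant pairs).
#' @export
map_full_pair <- function(reference, index, pair, config = resolver_config()) {
  refh <- .ref_handle(reference)
  p1 <- .full_placements(refh, index, pair$seq1[1])
  p2 <- .full_placements(refh, index, pair$seq2[1])
  geo <- .pe_concordant(p1, p2, nchar(pair$seq1[1]), config$concordance_range)
  status <- if (!is.null(geo)) "PE_mapped"
    else if (nrow(p1) && nrow(p2)) "SE_mapped_both"
    else if (nrow(p1)) "SE_mapped_read1"
    else if (nrow(p2)) "SE_mapped_read2"
    else "unmapped"
  list(full_status = status, read1 = p1, read2 = p2, geometry = geo)
}

#' Run both alignment passes over a dataset
#'
#' Pass 1 places each full-length read; pass 2 places the 5'-most
#' `config$seed_len` nt seed of each read on both strands. Results feed
#' [select_candidates()] and [classify_dataset()].
#'
#' @param reference Named character vector (or `chimera_ref` handle).
#' @param pairs Read-pair `data.frame`.
#' @param config A [resolver_config()].
#' @param index Optional prebuilt `reference_index` (k must equal
#'   `config$seed_len`).
#' @return A `pair_alignment` list: `status` data.frame (one row per pair:
#'   `pair_id`, `full_status`, per-read full-placement counts and first
#'   placement, per-read seed-hit counts and unique seed hit, `inner_distance`
#'   for concordant pairs), plus `placements` (per-pair placement tables) and
#'   the `config`/`index` used.
#' @export
align_dataset <- function(reference, pairs, config = resolver_config(),
                          index = NULL) {
  refh <- .ref_handle(reference)
  if (is.null(index)) index <- build_index(refh$seq, k = config$seed_len)
  if (index$k != config$seed_len) {
    stop("index k does not match config$seed_len", call. = FALSE)
  }
  n <- nrow(pairs)
  empty_col <- function(mode) vector(mode, n)
  st <- data.frame(
    pair_id = pairs$pair_id,
    full_status = character(n),
    r1_n_full = integer(n), r2_n_full = integer(n),
    r1_chrom = empty_col("character"), r1_start = rep(NA_integer_, n),
    r1_strand = empty_col("character"),
    r2_chrom = empty_col("character"), r2_start = rep(NA_integer_, n),
    r2_strand = empty_col("character"),
    inner_distance = rep(NA_integer_, n),
    r1_seed_n = integer(n), r1_seed_chrom = empty_col("character"),
    r1_seed_pos = rep(NA_integer_, n), r1_seed_strand = empty_col("character"),
    r2_seed_n = integer(n), r2_seed_chrom = empty_col("character"),
    r2_seed_pos = rep(NA_integer_, n), r2_seed_strand = empty_col("character"),
    stringsAsFactors = FALSE
  )
  placements <- vector("list", n)
  for (i in seq_len(n)) {
    mp <- map_full_pair(refh, index, pairs[i, , drop = FALSE], config)
    st$full_status[i] <- mp$full_status
    st$r1_n_full[i] <- nrow(mp$read1); st$r2_n_full[i] <- nrow(mp$read2)
    if (nrow(mp$read1)) {
      st$r1_chrom[i] <- mp$read1$chrom[1]; st$r1_start[i] <- mp$read1$pos[1]
      st$r1_strand[i] <- mp$read1$strand[1]
    }
    if (nrow(mp$read2)) {
      st$r2_chrom[i] <- mp$read2$chrom[1]; st$r2_start[i] <- mp$read2$pos[1]
      st$r2_strand[i] <- mp$read2$strand[1]
    }
    if (!is.null(mp$geometry)) st$inner_distance[i] <- mp$geometry$inner
    s1 <- map_exact(index, extract_seed(pairs$seq1[i], config$seed_len))
    s2 <- map_exact(index, extract_seed(pairs$seq2[i], config$seed_len))
    st$r1_seed_n[i] <- nrow(s1); st$r2_seed_n[i] <- nrow(s2)
    if (nrow(s1) == 1L) {
      st$r1_seed_chrom[i] <- s1$chrom; st$r1_seed_pos[i] <- s1$pos
      st$r1_seed_strand[i] <- s1$strand
    }
    if (nrow(s2) == 1L) {
      st$r2_seed_chrom[i] <- s2$chrom; st$r2_seed_pos[i] <- s2$pos
      st$r2_seed_strand[i] <- s2$strand
    }
    placements[[i]] <- list(read1 = mp$read1, read2 = mp$read2,
                            geometry = mp$geometry)
  }
  structure(list(status = st, placements = placements, config = config,
                 index = index),
            class = "pair_alignment")
}

#' Select candidate chimeric reads
#'
#' A read is a candidate iff its pair is not `PE_mapped`, its seed maps to
#' exactly one location ("accurately mapped": ambiguous seeds are dropped and
#' counted), and the full-length read has no exact placement (so the read
#' cannot extend over its whole length at the seed's location).
#'
#' @param pairs Read-pair `data.frame`.
#' @param aln A `pair_alignment` from [align_dataset()].
#' @return List with `candidates` (data.frame: `pair_id`, `read_end`, `seq`,
#'   `chrom`, `ref_start`, `strand`; one row per candidate read, seed offset
#'   is always 0) and `n_ambiguous_seeds` (dropped reads whose seed hit more
#'   than one location).
#' @export
select_candidates <- function(pairs, aln) {
  st <- aln$status
  stopifnot(identical(st$pair_id, pairs$pair_id))
  rows <- list()
  n_ambig <- 0L
  for (i in seq_len(nrow(st))) {
    if (st$full_status[i] == "PE_mapped") next
    for (end in 1:2) {
      seed_n <- if (end == 1L) st$r1_seed_n[i] else st$r2_seed_n[i]
      full_n <- if (end == 1L) st$r1_n_full[i] else st$r2_n_full[i]
      if (seed_n > 1L) { n_ambig <- n_ambig + 1L; next }
      if (seed_n == 1L && full_n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = st$pair_id[i],
          read_end = end,
          seq = if (end == 1L) pairs$seq1[i] else pairs$seq2[i],
          chrom = if (end == 1L) st$r1_seed_chrom[i] else st$r2_seed_chrom[i],
          ref_start = if (end == 1L) st$r1_seed_pos[i] else st$r2_seed_pos[i],
          strand = if (end == 1L) st$r1_seed_strand[i] else st$r2_seed_strand[i],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  cands <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(0), read_end = integer(0),
               seq = character(0), chrom = character(0),
               ref_start = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  list(candidates = cands, n_ambiguous_seeds = n_ambig)
}
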
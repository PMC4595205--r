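# Synthetic MDA paired-end read simulator with exact per-junction ground truth.
#
# Chimeric fragments are chains of reference pieces joined at junctions with a
# drawn orientation (inverted/direct), signed chimeric distance and intended
# microhomology (overlap). Microhomology cannot be left to chance in random
# sequence, so the simulator PLANTS it: for each junction it copies the former
# subsection's tail into the oriented window immediately preceding the
# following subsection's start, then forces the two boundary bases (the base
# just before the planted window and the former subsection's continuation
# base) to mismatch so the realized overlap and the breakpoint are exact.
# All plants are written into the reference before it is frozen; fragments are
# extracted from the frozen reference afterwards, so reads are always
# consistent with it. Ground truth is recorded in the frame of the read that
# observes each junction (junctions seen through read2 have swapped
# former/following roles, flipped strands and negated distance relative to the
# fragment frame).

.SIM_BASES <- c("A", "C", "G", "T")

#' Simulator configuration
#'
#' Defaults follow the conditions reported for large-scale human phi29 MDA
#' libraries: ~6.19% of pairs chimeric, level mixture 97.06/2.29/0.64%,
#' 70.7% inverted junctions, chimeric distance peaked near 275 nt within a
#' 0-5000 nt range, overlap peaked at 6 nt (most mass on 5-8 nt), PE-101
#' reads with a 300 +/- 30 nt inner insert.
#'
#' @param ref_length Reference length (bp), one chromosome named `chr1`.
#' @param n_pairs Number of read pairs.
#' @param chimera_fraction Fraction of pairs carrying at least one junction.
#' @param p_inverted Probability a junction is inverted (strands differ).
#' @param level_probs Probabilities of 1/2/3 chimeric events per chimeric
#'   pair; normalized internally.
#' @param dist_modes,dist_sds,dist_weights Two-component discretized-normal
#'   mixture for `|D|`; the primary mode mimics the 250-300 nt abundance peak,
#'   the broad secondary component fills the upper range.
#' @param dist_range `|D|` truncation interval (resampled into range).
#' @param overlap_mode,overlap_sd,overlap_max Intended overlap is drawn from a
#'   discretized normal on `0:overlap_max` centred at `overlap_mode`.
#' @param inner_mean,inner_sd Inner insert (gap between mates, nt), normal.
#' @param read_len Read length (nt).
#' @param error_rate Per-base substitution error rate on reads.
#' @param junction_region `"fragment"` places breakpoints uniformly over the
#'   whole fragment (the equal-probability-per-nucleotide hypothesis);
#'   `"read"` restricts them to the two sequenced read windows.
#' @param seed RNG seed; same config (incl. seed) gives identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(ref_length = 200000L,
                       n_pairs = 1000L,
                       chimera_fraction = 0.0619,
                       p_inverted = 0.707,
                       level_probs = c(0.9706, 0.0229, 0.0064),
                       dist_modes = c(275, 1800),
                       dist_sds = c(60, 900),
                       dist_weights = c(0.7, 0.3),
                       dist_range = c(1L, 5000L),
                       overlap_mode = 6L,
                       overlap_sd = 1.5,
                       overlap_max = 15L,
                       inner_mean = 300,
                       inner_sd = 30,
                       read_len = 101L,
                       error_rate = 0,
                       junction_region = c("fragment", "read"),
                       seed = 1L) {
  cfg <- list(ref_length = as.integer(ref_length), n_pairs = as.integer(n_pairs),
              chimera_fraction = chimera_fraction, p_inverted = p_inverted,
              level_probs = level_probs / sum(level_probs),
              dist_modes = dist_modes, dist_sds = dist_sds,
              dist_weights = dist_weights / sum(dist_weights),
              dist_range = as.integer(dist_range),
              overlap_mode = overlap_mode, overlap_sd = overlap_sd,
              overlap_max = as.integer(overlap_max),
              inner_mean = inner_mean, inner_sd = inner_sd,
              read_len = as.integer(read_len), error_rate = error_rate,
              junction_region = match.arg(junction_region),
              seed = as.integer(seed))
  stopifnot(cfg$ref_length > 0L, cfg$n_pairs >= 0L,
            cfg$chimera_fraction >= 0, cfg$chimera_fraction <= 1,
            cfg$p_inverted >= 0, cfg$p_inverted <= 1,
            all(cfg$level_probs >= 0), cfg$dist_range[1] >= 1L,
            cfg$read_len > 0L, cfg$error_rate >= 0, cfg$error_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic reference, optionally with planted homology pairs
#'
#' The base sequence is i.i.d. uniform A/C/G/T. Each homology plant copies the
#' `o` bases ending just before locus `a` onto the `o` bases ending just
#' before locus `b` (0-based loci), so an intended overlap of `o` nt exists
#' between a former-tail locus and the bases preceding a following-start
#' locus; `inverted = TRUE` writes the reverse complement instead.
#'
#' @param length Reference length (bp).
#' @param seed RNG seed (set internally for reproducibility).
#' @param homology_plants Optional list of plants, each
#'   `list(loci = c(a, b), o = <nt>, inverted = FALSE)`.
#' @return Named character vector with one sequence `chr1`.
#' @export
make_reference <- function(length, seed = 1L, homology_plants = NULL) {
  stopifnot(length > 0L)
  set.seed(seed)
  chars <- sample(.SIM_BASES, length, replace = TRUE)
  if (!is.null(homology_plants)) {
    windows <- lapply(homology_plants, function(p) {
      stopifnot(length(p$loci) == 2L, p$o >= 1L)
      a <- p$loci[1]; b <- p$loci[2]
      if (a - p$o < 0L || b - p$o < 0L || a > length || b > length) {
        stop("plant loci out of range", call. = FALSE)
      }
      c((b - p$o):(b - 1L))
    })
    allw <- unlist(windows)
    if (anyDuplicated(allw)) stop("overlapping plant loci", call. = FALSE)
    for (p in homology_plants) {
      a <- p$loci[1]; b <- p$loci[2]
      src <- chars[(a - p$o + 1L):a]
      if (isTRUE(p$inverted)) {
        src <- rev(chartr("ACGT", "TGCA", src))
      }
      chars[(b - p$o + 1L):b] <- src
    }
  }
  c(chr1 = paste0(chars, collapse = ""))
}

# draw |D| values from the truncated mixture, then attach random signs
.draw_distance <- function(n, cfg) {
  out <- integer(n)
  need <- seq_len(n)
  while (length(need)) {
    comp <- sample.int(length(cfg$dist_weights), length(need), replace = TRUE,
                       prob = cfg$dist_weights)
    v <- as.integer(round(stats::rnorm(length(need), cfg$dist_modes[comp],
                                       cfg$dist_sds[comp])))
    ok <- v >= cfg$dist_range[1] & v <= cfg$dist_range[2]
    out[need[ok]] <- v[ok]
    need <- need[!ok]
  }
  out * sample(c(1L, -1L), n, replace = TRUE)
}

# intended overlap lengths from the discretized normal
.draw_overlap <- function(n, cfg) {
  support <- 0:cfg$overlap_max
  w <- stats::dnorm(support, cfg$overlap_mode, cfg$overlap_sd)
  sample(support, n, replace = TRUE, prob = w)
}

.flip <- function(s) ifelse(s == "+", "-", "+")

# Chain geometry for a junction plan. `plan` carries piece_lens (k+1 values),
# and per-junction orientation/distance. Returns per-piece start/last
# coordinates, strands, and forward intervals, relative to g0.
.chain_coords <- function(plan, g0) {
  k <- length(plan$piece_lens) - 1L
  p <- integer(k + 1L); e <- integer(k + 1L); s <- character(k + 1L)
  lo <- integer(k + 1L); hi <- integer(k + 1L)
  s[1] <- "+"; p[1] <- g0
  for (i in seq_len(k + 1L)) {
    l <- plan$piece_lens[i]
    if (s[i] == "+") { e[i] <- p[i] + l - 1L; lo[i] <- p[i]; hi[i] <- e[i] }
    else { e[i] <- p[i] - l + 1L; lo[i] <- e[i]; hi[i] <- p[i] }
    if (i <= k) {
      s[i + 1L] <- if (plan$orientation[i] == "inverted") .flip(s[i]) else s[i]
      p[i + 1L] <- e[i] - plan$distance[i]
    }
  }
  list(p = p, e = e, s = s, lo = lo, hi = hi)
}

# Observation-frame junction parameters for junction i of a chain.
# frame "read2" swaps former/following, flips strands and negates D.
.obs_junction <- function(ch, i, frame) {
  if (frame == "read2") {
    list(sf = .flip(ch$s[i + 1L]), e = ch$p[i + 1L],
         sg = .flip(ch$s[i]), c = ch$e[i],
         former_piece = i + 1L, following_piece = i)
  } else {
    list(sf = ch$s[i], e = ch$e[i],
         sg = ch$s[i + 1L], c = ch$p[i + 1L],
         former_piece = i, following_piece = i + 1L)
  }
}

# Coordinates a plant for one junction touches. Writes: the o-base window
# preceding the following start (oriented), the boundary base before that
# window, and the former subsection's continuation base. Reads (critical):
# the former tail source, the base before the tail, and the following first
# base. Returns list(window, wb, cc, reads).
.plant_coords <- function(obs, o) {
  window <- if (o > 0L) {
    if (obs$sg == "+") (obs$c - o):(obs$c - 1L) else (obs$c + 1L):(obs$c + o)
  } else integer(0)
  wb <- if (obs$sg == "+") obs$c - o - 1L else obs$c + o + 1L
  cc <- if (obs$sf == "+") obs$e + 1L else obs$e - 1L
  tail_src <- if (o > 0L) {
    if (obs$sf == "+") (obs$e - o + 1L):obs$e else obs$e:(obs$e + o - 1L)
  } else integer(0)
  tb <- if (obs$sf == "+") obs$e - o else obs$e + o
  list(window = window, wb = wb, cc = cc,
       reads = c(tail_src, tb, obs$c))
}

# oriented single character at 0-based coord
.or_char <- function(chars, coord, strand) {
  ch <- chars[coord + 1L]
  if (strand == "-") chartr("ACGTN", "TGCAN", ch) else ch
}

# Apply the plant for one junction to the mutable reference `chars`.
# Assumes coordinates were bounds/occupancy checked.
.apply_plant <- function(chars, obs, o) {
  if (o > 0L) {
    tail_or <- if (obs$sf == "+") {
      chars[(obs$e - o + 1L):obs$e + 1L]
    } else {
      rev(chartr("ACGT", "TGCA", chars[obs$e:(obs$e + o - 1L) + 1L]))
    }
    # write so the oriented window (in the following's reading direction)
    # equals the former tail
    if (obs$sg == "+") {
      chars[((obs$c - o):(obs$c - 1L)) + 1L] <- tail_or
    } else {
      chars[((obs$c + 1L):(obs$c + o)) + 1L] <- rev(chartr("ACGT", "TGCA", tail_or))
    }
  }
  pc <- .plant_coords(obs, o)
  # left boundary: base before the window must differ from the former base
  # before the tail, so the realized overlap is exactly o
  tb_or <- .or_char(chars, if (obs$sf == "+") obs$e - o else obs$e + o, obs$sf)
  new_or <- sample(setdiff(.SIM_BASES, tb_or), 1L)
  chars[pc$wb + 1L] <- if (obs$sg == "-") chartr("ACGT", "TGCA", new_or) else new_or
  # right boundary: the former's continuation base must differ from the
  # following's first base, so seed extension stops exactly at the breakpoint
  if (pc$cc != obs$c) {
    first_or <- .or_char(chars, obs$c, obs$sg)
    new_or <- sample(setdiff(.SIM_BASES, first_or), 1L)
    chars[pc$cc + 1L] <- if (obs$sf == "-") chartr("ACGT", "TGCA", new_or) else new_or
  }
  chars
}

# Sample a junction plan for one chimeric pair: breakpoint offsets, per
# junction orientation / signed D / intended overlap. `fl` fragment length.
.sample_plan <- function(cfg, fl, n_junc) {
  region <- if (cfg$junction_region == "read") {
    r1 <- seq_len(min(cfg$read_len, fl) - 1L)
    r2 <- seq.int(max(fl - cfg$read_len + 1L, 1L), fl - 1L)
    unique(c(r1, r2))
  } else {
    seq_len(fl - 1L)
  }
  if (length(region) < n_junc) return(NULL)
  offs <- sort(region[sample.int(length(region), n_junc)])
  orientation <- ifelse(stats::runif(n_junc) < cfg$p_inverted,
                        "inverted", "direct")
  distance <- .draw_distance(n_junc, cfg)
  overlap <- .draw_overlap(n_junc, cfg)
  list(offsets = offs, piece_lens = diff(c(0L, offs, fl)),
       orientation = orientation, distance = distance, overlap = overlap)
}

# frame observing the junction at fragment offset b
.junction_frame <- function(b, fl, read_len) {
  if (b < read_len) "read1"
  else if (b >= fl - read_len + 1L) "read2"
  else "insert"
}

# reject plans where a direct junction is reference-contiguous (no junction)
.plan_degenerate <- function(ch, plan) {
  k <- length(plan$distance)
  for (i in seq_len(k)) {
    if (plan$orientation[i] == "direct") {
      if (ch$s[i] == "+" && plan$distance[i] == -1L) return(TRUE)
      if (ch$s[i] == "-" && plan$distance[i] == 1L) return(TRUE)
    }
  }
  FALSE
}

#' Construct one chimeric fragment from a reference
#'
#' Samples a junction plan (breakpoints, orientations, signed distances) and
#' extracts the chained pieces from the given, already frozen reference.
#' Overlaps realize only where the reference provides homology; use
#' [simulate_dataset()] for planted, exact overlaps.
#'
#' @param reference Named character vector (single chromosome used).
#' @param config A [sim_config()].
#' @param fragment_len Fragment length; drawn from the configured insert model
#'   when `NULL`.
#' @param n_junctions Number of junctions; drawn from `level_probs` when `NULL`.
#' @return List with `fragment` (sequence), `chrom`, `plan`, `chain`, and
#'   `junctions` (truth data.frame as in [simulate_dataset()]).
#' @export
make_chimeric_fragment <- function(reference, config = sim_config(),
                                   fragment_len = NULL, n_junctions = NULL) {
  chrom <- names(reference)[1]
  L <- nchar(reference[[1]])
  fl <- if (is.null(fragment_len)) {
    max(2L * config$read_len,
        as.integer(round(stats::rnorm(1, config$inner_mean, config$inner_sd))) +
          2L * config$read_len)
  } else as.integer(fragment_len)
  nj <- if (is.null(n_junctions)) {
    sample(1:3, 1L, prob = config$level_probs)
  } else as.integer(n_junctions)
  for (try in 1:60) {
    plan <- .sample_plan(config, fl, nj)
    if (is.null(plan)) next
    ch0 <- .chain_coords(plan, 0L)
    if (.plan_degenerate(ch0, plan)) next
    pad <- max(plan$overlap) + 2L
    g_lo <- pad - min(ch0$lo); g_hi <- L - 1L - max(ch0$hi) - pad
    if (g_hi < g_lo) next
    g0 <- sample(g_lo:g_hi, 1L)
    ch <- .chain_coords(plan, g0)
    chars <- strsplit(reference[[1]], "")[[1]]
    frag <- .extract_fragment(chars, ch, plan)
    truth <- .junction_truth(reference, chrom, ch, plan, fl, config$read_len)
    return(list(fragment = frag, chrom = chrom, plan = plan, chain = ch,
                junctions = truth))
  }
  stop("could not place a chimeric fragment after 60 attempts", call. = FALSE)
}

.extract_fragment <- function(chars, ch, plan) {
  parts <- vapply(seq_along(plan$piece_lens), function(i) {
    piece <- chars[(ch$lo[i]:ch$hi[i]) + 1L]
    if (ch$s[i] == "-") piece <- rev(chartr("ACGTN", "TGCAN", piece))
    paste0(piece, collapse = "")
  }, character(1))
  paste0(parts, collapse = "")
}

# truth rows for every junction of a chain, in observation frame
.junction_truth <- function(reference, chrom, ch, plan, fl, read_len) {
  k <- length(plan$distance)
  rows <- lapply(seq_len(k), function(i) {
    b <- plan$offsets[i]
    frame <- .junction_frame(b, fl, read_len)
    obs <- .obs_junction(ch, i, if (frame == "read2") "read2" else "read1")
    fp <- obs$former_piece
    former <- list(chrom = chrom, ref_start = ch$lo[fp],
                   ref_end = ch$hi[fp] + 1L, strand = obs$sf,
                   read_start = 0L, read_end = plan$piece_lens[fp])
    following <- list(chrom = chrom, strand = obs$sg, start_coord = obs$c)
    data.frame(
      junction_index = i, frag_offset = b, obs_frame = frame, chrom = chrom,
      former_strand = obs$sf, following_strand = obs$sg,
      former_end_coord = obs$e, following_start_coord = obs$c,
      distance = obs$e - obs$c,
      orientation = if (obs$sf == obs$sg) "direct" else "inverted",
      planted_overlap = plan$overlap[i],
      realized_overlap = oracle_overlap(reference, former, following),
      distance_frag = plan$distance[i],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Emit a read pair from a fragment
#'
#' `read1` is the first `read_len` bases of the fragment, `read2` the reverse
#' complement of its last `read_len` bases (reads overlap when the fragment is
#' shorter than `2 * read_len`). Substitution errors are applied per base;
#' qualities are a constant string.
#'
#' @param fragment Fragment sequence.
#' @param read_len Read length (nt); must not exceed the fragment length.
#' @param error_rate Per-base substitution probability.
#' @param pair_id Pair identifier.
#' @return One-row read-pair `data.frame`.
#' @export
make_read_pair <- function(fragment, read_len = 101L, error_rate = 0,
                           pair_id = "pair1") {
  fl <- nchar(fragment)
  if (fl < read_len) stop("fragment shorter than the read length", call. = FALSE)
  r1 <- substr(fragment, 1L, read_len)
  r2 <- revcomp(substr(fragment, fl - read_len + 1L, fl))
  if (error_rate > 0) {
    mutate <- function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(ch)) < error_rate)
      for (j in hit) {
        ch[j] <- sample(setdiff(.SIM_BASES, ch[j]), 1L)
      }
      paste0(ch, collapse = "")
    }
    r1 <- mutate(r1); r2 <- mutate(r2)
  }
  q <- strrep("I", read_len)
  data.frame(pair_id = pair_id, seq1 = r1, qual1 = q, seq2 = r2, qual2 = q,
             stringsAsFactors = FALSE)
}

#' Simulate a full paired-end dataset with ground truth
#'
#' Generates the reference (with all junction homologies planted before
#' freezing), normal and chimeric fragments, reads, and per-pair / per-junction
#' truth tables. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `reference` (named character vector), `pairs` (read-pair
#'   `data.frame`), `truth_pairs` (`pair_id`, `is_chimera`, `level`,
#'   `chimera_type`, `fragment_len`, `inner_insert`, `n_junctions`), and
#'   `truth_junctions` (one row per junction, observation frame: `pair_id`,
#'   `junction_index`, `frag_offset`, `obs_frame`, `chrom`, strands, end/start
#'   coordinates, signed `distance`, `orientation`, `planted_overlap`,
#'   `realized_overlap`, `distance_frag`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  L <- config$ref_length
  rl <- config$read_len
  n <- config$n_pairs
  chars <- sample(.SIM_BASES, L, replace = TRUE)
  occupied <- logical(L)

  is_chim <- stats::runif(n) < config$chimera_fraction
  inner <- pmax(10L, as.integer(round(stats::rnorm(n, config$inner_mean,
                                                   config$inner_sd))))
  fls <- inner + 2L * rl
  plans <- vector("list", n)
  chains <- vector("list", n)

  for (i in seq_len(n)) {
    fl <- fls[i]
    if (!is_chim[i]) {
      g0 <- sample.int(L - fl + 1L, 1L) - 1L
      chains[[i]] <- .chain_coords(list(piece_lens = fl, orientation = character(0),
                                        distance = integer(0)), g0)
      plans[[i]] <- list(offsets = integer(0), piece_lens = fl,
                         orientation = character(0), distance = integer(0),
                         overlap = integer(0))
      next
    }
    nj <- sample(1:3, 1L, prob = config$level_probs)
    placed <- FALSE
    for (try in 1:80) {
      plan <- .sample_plan(config, fl, nj)
      if (is.null(plan)) break
      ch0 <- .chain_coords(plan, 0L)
      if (.plan_degenerate(ch0, plan)) next
      pad <- config$overlap_max + 4L
      g_lo <- pad - min(ch0$lo); g_hi <- L - 1L - max(ch0$hi) - pad
      if (g_hi < g_lo) next
      g0 <- sample(g_lo:g_hi, 1L)
      ch <- .chain_coords(plan, g0)
      # bounds / occupancy check over all write coordinates of the pair
      coords <- lapply(seq_len(nj), function(j) {
        b <- plan$offsets[j]
        frame <- .junction_frame(b, fl, rl)
        obs <- .obs_junction(ch, j, if (frame == "read2") "read2" else "read1")
        .plant_coords(obs, plan$overlap[j])
      })
      writes <- unlist(lapply(coords, function(pc) c(pc$window, pc$wb, pc$cc)))
      crit <- unique(c(writes, unlist(lapply(coords, `[[`, "reads"))))
      if (any(writes < 0L) || any(writes >= L) ||
          any(crit < 0L) || any(crit >= L) || any(occupied[writes + 1L])) next
      # commit: apply plants junction by junction, then lock the critical set
      for (j in seq_len(nj)) {
        b <- plan$offsets[j]
        frame <- .junction_frame(b, fl, rl)
        obs <- .obs_junction(ch, j, if (frame == "read2") "read2" else "read1")
        chars <- .apply_plant(chars, obs, plan$overlap[j])
      }
      occupied[crit + 1L] <- TRUE
      plans[[i]] <- plan
      chains[[i]] <- ch
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf("could not place chimeric pair %d after 80 attempts", i),
           call. = FALSE)
    }
  }

  reference <- c(chr1 = paste0(chars, collapse = ""))

  pair_ids <- sprintf("sim%06d", seq_len(n))
  pairs <- vector("list", n)
  tj <- vector("list", n)
  tp <- vector("list", n)
  for (i in seq_len(n)) {
    frag <- .extract_fragment(chars, chains[[i]], plans[[i]])
    pairs[[i]] <- make_read_pair(frag, rl, config$error_rate, pair_ids[i])
    nj <- length(plans[[i]]$distance)
    type <- NA_character_
    if (nj > 0L) {
      truth <- .junction_truth(reference, "chr1", chains[[i]], plans[[i]],
                               fls[i], rl)
      tj[[i]] <- cbind(data.frame(pair_id = pair_ids[i],
                                  stringsAsFactors = FALSE), truth)
      frames <- truth$obs_frame
      type <- if (all(frames == "insert")) "insertion"
              else if (all(frames != "insert")) "pair_end"
              else "mixed"
    }
    tp[[i]] <- data.frame(pair_id = pair_ids[i], is_chimera = nj > 0L,
                          level = if (nj > 0L) min(nj, 3L) else NA_integer_,
                          chimera_type = type, fragment_len = fls[i],
                          inner_insert = fls[i] - 2L * rl, n_junctions = nj,
                          stringsAsFactors = FALSE)
  }
  tj <- tj[!vapply(tj, is.null, logical(1))]
  list(reference = reference,
       pairs = do.call(rbind, pairs),
       truth_pairs = do.call(rbind, tp),
       truth_junctions = if (length(tj)) do.call(rbind, tj) else NULL)
}

#' Brute-force overlap oracle
#'
#' Independent per-base backward scan used to cross-check [compute_overlap()]
#' and to record realized overlaps in ground truth. Shares no code with the
#' resolver: characters are compared one at a time via `substr`.
#'
#' @param reference Named character vector.
#' @param former Segment-like list: `chrom`, `ref_start`, `ref_end`, `strand`,
#'   and optionally `read_start`/`read_end` (for the cap; the ref interval
#'   length is used otherwise).
#' @param following Segment-like list: `chrom`, `strand`, and either
#'   `start_coord` (forward coordinate of its first matched base) or a
#'   `ref_start`/`ref_end` interval.
#' @return Overlap length in nt.
#' @export
oracle_overlap <- function(reference, former, following) {
  seq <- reference[[former$chrom]]
  n <- nchar(seq)
  comp <- function(ch) chartr("ACGTN", "TGCAN", ch)
  base_at <- function(coord, strand) {
    if (coord < 0L || coord >= n) return(NA_character_)
    ch <- substr(seq, coord + 1L, coord + 1L)
    if (strand == "-") comp(ch) else ch
  }
  cap <- if (!is.null(former$read_end)) former$read_end - former$read_start
         else former$ref_end - former$ref_start
  c0 <- if (!is.null(following$start_coord)) following$start_coord
        else if (following$strand == "+") following$ref_start
        else following$ref_end - 1L
  L <- 0L
  while (L < cap) {
    # former's base L+1 from its end, in its reading direction
    fb <- if (former$strand == "+") base_at(former$ref_end - 1L - L, "+")
          else base_at(former$ref_start + L, "-")
    # base L+1 before the following's first matched base, in its direction
    pb <- if (following$strand == "+") base_at(c0 - 1L - L, "+")
          else base_at(c0 + 1L + L, "-")
    if (is.na(fb) || is.na(pb) || fb != pb) break
    L <- L + 1L
  }
  L
}
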
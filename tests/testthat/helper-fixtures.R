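# Shared fixtures for the test suite. Expensive simulations are memoized in
# this environment so several test files can reuse one dataset.

.fixture_env <- new.env(parent = emptyenv())

# small end-to-end dataset: 150 chimeric pairs on a 100-kb reference
small_sim <- function() {
  if (is.null(.fixture_env$small_sim)) {
    cfg <- sim_config(ref_length = 100000L, n_pairs = 150L,
                      chimera_fraction = 1, junction_region = "read",
                      seed = 101L)
    .fixture_env$small_sim <- simulate_dataset(cfg)
  }
  .fixture_env$small_sim
}

small_detect <- function() {
  if (is.null(.fixture_env$small_detect)) {
    sim <- small_sim()
    .fixture_env$small_detect <-
      detect_chimeras(sim$reference, sim$pairs, resolver_config())
  }
  .fixture_env$small_detect
}

# a constructed two-part chimeric read on a fresh random reference:
# former = ref[a, a + a_len), following per strand, with the boundary bases
# forced to mismatch so the breakpoint is unambiguous
build_two_part_read <- function(ref_len = 4000L, a = 200L, a_len = 60L,
                                b = 700L, b_strand = "+", seed = 9L) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), ref_len, replace = TRUE)
  read_len <- 101L
  b_len <- read_len - a_len
  former <- chars[(a + 1L):(a + a_len)]
  if (b_strand == "+") {
    following <- chars[(b + 1L):(b + b_len)]
    # force a mismatch at the junction so extension stops exactly at a_len
    cont <- chars[a + a_len + 1L]
    if (following[1] == cont) {
      chars[b + 1L] <- setdiff(c("A", "C", "G", "T"), cont)[1]
      following[1] <- chars[b + 1L]
    }
  } else {
    win <- chars[(b - b_len + 1L):b]
    following <- rev(chartr("ACGT", "TGCA", win))
    cont <- chars[a + a_len + 1L]
    if (following[1] == cont) {
      new_first <- setdiff(c("A", "C", "G", "T"), cont)[1]
      chars[b] <- chartr("ACGT", "TGCA", new_first)
      following[1] <- new_first
    }
  }
  reference <- c(chr1 = paste0(chars, collapse = ""))
  read <- paste0(c(former, following), collapse = "")
  anchor <- list(chrom = "chr1", ref_start = a, strand = "+")
  list(reference = reference, read = read, anchor = anchor,
       a = a, a_len = a_len, b = b, b_len = b_len, b_strand = b_strand)
}
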
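test_that("map_exact agrees with a naive full scan on both strands", {
  ref <- make_reference(3000L, seed = 11L)
  idx <- build_index(ref, k = 30L)
  seq_chars <- strsplit(unname(ref), "")[[1]]
  set.seed(12)
  for (i in 1:25) {
    pos <- sample(0:(3000L - 30L), 1)
    q <- substr(unname(ref), pos + 1L, pos + 30L)
    minus <- runif(1) < 0.5
    query <- if (minus) revcomp(q) else q
    hits <- map_exact(idx, query)

    # naive scan: every forward window equal to the query or its revcomp
    naive <- data.frame(pos = integer(0), strand = character(0))
    for (p in 0:(3000L - 30L)) {
      w <- paste0(seq_chars[(p + 1L):(p + 30L)], collapse = "")
      if (w == query) naive <- rbind(naive, data.frame(pos = p, strand = "+"))
      if (w == revcomp(query)) naive <- rbind(naive, data.frame(pos = p, strand = "-"))
    }
    expect_identical(nrow(hits), nrow(naive))
    o1 <- order(hits$pos, hits$strand); o2 <- order(naive$pos, naive$strand)
    expect_identical(hits$pos[o1], naive$pos[o2])
    expect_identical(hits$strand[o1], naive$strand[o2])
  }
})

test_that("extract_seed returns the 5'-most bases", {
  expect_identical(extract_seed(strrep("ACGT", 30), 30L),
                   substr(strrep("ACGT", 30), 1, 30))
  expect_error(extract_seed("ACGT", 30L))
})

test_that("a concordant pair maps as PE_mapped and is never a candidate", {
  ref <- make_reference(5000L, seed = 21L)
  cfg <- resolver_config()
  s <- unname(ref)
  f_start <- 1000L
  inner <- 300L
  r_start <- f_start + 101L + inner
  pairs <- data.frame(
    pair_id = "conc",
    seq1 = substr(s, f_start + 1L, f_start + 101L),
    qual1 = strrep("I", 101),
    seq2 = revcomp(substr(s, r_start + 1L, r_start + 101L)),
    qual2 = strrep("I", 101),
    stringsAsFactors = FALSE
  )
  aln <- align_dataset(ref, pairs, cfg)
  expect_identical(aln$status$full_status, "PE_mapped")
  expect_identical(aln$status$inner_distance, inner)
  cand <- select_candidates(pairs, aln)
  expect_identical(nrow(cand$candidates), 0L)
})

test_that("a chimeric read yields a candidate with a uniquely mapped seed", {
  tp <- build_two_part_read()
  pairs <- data.frame(
    pair_id = "chim",
    seq1 = tp$read, qual1 = strrep("I", 101),
    seq2 = revcomp(substr(unname(tp$reference), 3001, 3101)),
    qual2 = strrep("I", 101),
    stringsAsFactors = FALSE
  )
  aln <- align_dataset(tp$reference, pairs, resolver_config())
  expect_false(aln$status$full_status == "PE_mapped")
  cand <- select_candidates(pairs, aln)
  expect_identical(nrow(cand$candidates), 1L)
  expect_identical(cand$candidates$read_end, 1L)
  expect_identical(cand$candidates$ref_start, tp$a)
  expect_identical(cand$candidates$strand, "+")
})
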
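LF <- "GCAGTTCACGGTACCA"
RF <- "TGGACCTGAACGGTCT"

test_that("a perfectly constructed read yields its cassette", {
  cassette <- "ACGTACGTACGTACGTACGTACGT"
  reads <- make_reads(cassette, LF, RF)
  pool <- extract_cassettes(reads, LF, RF, 24)
  expect_identical(pool$cassettes, cassette)
  expect_equal(pool$n_retained, 1)
  expect_equal(sum(pool$reject_counts), 0)
})

test_that("rejections are counted by the failed filter", {
  cassette <- "ACGTACGTACGTACGTACGTACGT"
  # right flank deleted
  reads <- list(id = "r1", sequence = paste0(LF, cassette),
                qualities = list(rep(30L, 16 + 24)))
  pool <- extract_cassettes(reads, LF, RF, 24)
  expect_equal(pool$n_retained, 0)
  expect_equal(unname(pool$reject_counts["no_right_flank"]), 1L)

  # no left flank at all
  reads <- make_reads(cassette, strrep("A", 16), RF)
  pool <- extract_cassettes(reads, LF, RF, 24)
  expect_equal(unname(pool$reject_counts["no_left_flank"]), 1L)

  # wrong spacing between flanks
  reads <- make_reads(substr(cassette, 1, 20), LF, RF)
  pool <- extract_cassettes(reads, LF, RF, 24)
  expect_equal(unname(pool$reject_counts["bad_length"]), 1L)

  # ambiguous base inside the cassette
  casN <- paste0("ACGTACGTACGTACGTACGTACG", "N")
  reads <- make_reads(casN, LF, RF)
  pool <- extract_cassettes(reads, LF, RF, 24)
  expect_equal(unname(pool$reject_counts["ambiguous_base"]), 1L)

  # low mean quality over the cassette
  reads <- make_reads(cassette, LF, RF, q = 10L)
  pool <- extract_cassettes(reads, LF, RF, 24, min_mean_q = 20)
  expect_equal(unname(pool$reject_counts["low_quality"]), 1L)
})

test_that("a pool with a known number of corrupted reads retains the rest", {
  set.seed(4)
  cassettes <- vapply(1:1000, function(i) random_dna(24), "")
  seqs <- paste0(LF, cassettes, RF)
  corrupt <- sample.int(1000, 100)
  # scramble the left flank beyond the mismatch allowance
  substr(seqs[corrupt], 1, 8) <- strrep("T", 8)
  reads <- list(id = sprintf("r%04d", 1:1000), sequence = seqs,
                qualities = lapply(nchar(seqs), function(L) rep(30L, L)))
  pool <- extract_cassettes(reads, LF, RF, 24, max_flank_mismatch = 1)
  expect_equal(pool$n_retained, 900)
  expect_equal(pool$n_retained + sum(pool$reject_counts), pool$n_input)
})

test_that("extraction is conservative and orientation-idempotent", {
  cfg <- selection_sim_config(n_reads = 300, rounds = 2, seed = 9,
                              per_base_error = 0.01,
                              low_q_tail_fraction = 0.1)
  dir <- withr::local_tempdir()
  sim <- gen_repsa_pool(cfg, dir)
  reads <- read_fastq(sim$fastq_paths[3])
  pool <- extract_cassettes(reads, cfg$left_flank, cfg$right_flank, 24)
  expect_equal(pool$n_retained + sum(pool$reject_counts), pool$n_input)
  expect_true(all(nchar(pool$cassettes) == 24))
  expect_false(any(grepl("[^ACGT]", pool$cassettes)))

  # read-wise reverse complement of the whole pool changes nothing
  rc_reads <- list(id = reads$id, sequence = revcomp(reads$sequence),
                   qualities = lapply(reads$qualities, rev))
  pool_rc <- extract_cassettes(rc_reads, cfg$left_flank, cfg$right_flank, 24)
  expect_identical(pool$cassettes, pool_rc$cassettes)
  expect_identical(pool$reject_counts, pool_rc$reject_counts)
})

test_that("every retained cassette re-embeds in its source read", {
  cfg <- selection_sim_config(n_reads = 200, rounds = 1, seed = 13,
                              per_base_error = 0.005)
  sim <- gen_repsa_pool(cfg)
  reads <- sim$reads[[2]]
  pool <- extract_cassettes(reads, cfg$left_flank, cfg$right_flank, 24,
                            max_flank_mismatch = 1)
  embedded <- paste0(cfg$left_flank, pool$cassettes, cfg$right_flank)
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  # each retained cassette must come from a read matching its embedding
  # within the allowed flank mismatches (2 flanks x 1 mismatch)
  ok <- vapply(embedded, function(e) {
    any(vapply(reads$sequence, function(r) {
      nchar(r) == nchar(e) && min(hamming(r, e), hamming(revcomp(r), e)) <= 2
    }, TRUE))
  }, TRUE)
  expect_true(all(ok))
})

test_that("empty input yields an empty pool, not an error", {
  reads <- list(id = character(0), sequence = character(0),
                qualities = list())
  pool <- extract_cassettes(reads, LF, RF, 24)
  expect_equal(pool$n_input, 0)
  expect_equal(pool$n_retained, 0)
})

test_that("cassette files and stats sidecars are written", {
  pool <- extract_cassettes(make_reads("ACGTACGTACGTACGTACGTACGT", LF, RF),
                            LF, RF, 24)
  path <- withr::local_tempfile(fileext = ".txt")
  write_cassettes(pool, path)
  expect_identical(readLines(path), pool$cassettes)
  stats <- jsonlite::read_json(paste0(path, ".stats.json"))
  expect_equal(stats$n_retained, 1)
})
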
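test_that("log-odds scoring matches closed forms", {
  pw <- new_pwm(matrix(c(0.7, 0.1, 0.1, 0.1), nrow = 1))
  expect_equal(score_sequence(pw, "A"), log2(0.7 / 0.25))
  expect_equal(score_sequence(pw, "C"), log2(0.1 / 0.25))

  # PWM equal to the background scores 0 for any sequence
  bg <- c(0.2, 0.3, 0.3, 0.2)
  flat <- new_pwm(matrix(rep(bg, each = 6), nrow = 6), background = bg)
  expect_equal(score_sequence(flat, "ACGTGC"), 0)

  # palindromized PWM scores a sequence and its reverse complement equally
  pal <- palindromize(make_random_pwm(8, seed = 2))
  set.seed(9)
  for (i in 1:10) {
    s <- random_dna(8)
    expect_equal(score_sequence(pal, s), score_sequence(pal, revcomp(s)))
  }
})

test_that("exact p-values match closed forms and brute force", {
  pw <- new_pwm(matrix(c(0.7, 0.1, 0.1, 0.1), nrow = 1))
  m <- score_model(pw, rep(0.25, 4))
  expect_equal(hit_pvalue(m, score_sequence(pw, "A")), 0.25)
  expect_equal(hit_pvalue(m, -1e6), 1)            # below-minimum score
  # above the maximum achievable: the point mass at the maximum, never 0
  expect_equal(hit_pvalue(m, 1e6), 0.25)

  # exhaustive brute-force oracle across widths and backgrounds
  for (w in 1:8) {
    for (case in 1:2) {
      bg <- if (case == 1) rep(0.25, 4) else c(0.155, 0.345, 0.345, 0.155)
      pwm <- make_random_pwm(w, seed = 10 * w + case)
      m <- score_model(pwm, bg, granularity = 100)
      set.seed(w + case)
      test_scores <- unique(c(
        min(which(m$dist > 0)) - 1 + m$offset,
        sample(seq_along(m$tail_p), min(20, length(m$tail_p))) - 1 + m$offset
      ))
      dp <- hit_pvalue(m, test_scores, integer_score = TRUE)
      bf <- brute_force_pvalues(m, bg, test_scores)
      expect_lt(max(abs(dp - bf)), 1e-12)
    }
  }
})

test_that("finer granularity tightens the integerization error", {
  pwm <- make_random_pwm(8, seed = 4)
  set.seed(5)
  seqs <- vapply(1:20, function(i) random_dna(8), "")
  true_scores <- vapply(seqs, function(s) score_sequence(pwm, s), 0)
  gap <- vapply(c(10, 100, 1000), function(g) {
    m <- score_model(pwm, rep(0.25, 4), granularity = g)
    ints <- vapply(seqs, function(s) {
      sum(m$s_int[cbind(1:8, dna_codes(s))])
    }, 0)
    max(abs(ints / g - true_scores))
  }, 0)
  expect_true(all(diff(gap) <= 0))
  expect_lt(gap[3], 8 / (2 * 1000) + 1e-12)   # round-trip bound w/(2g)
})

test_that("scanning recovers planted sites on both strands", {
  g <- gen_genome(genome_sim_config(
    length = 20000,
    planted_sites = data.frame(sequence = WT_CONSENSUS,
                               position = c(984, 7321), strand = c("+", "-")),
    seed = 2
  ))
  pwm <- palindromize(literal_pwm(WT_CONSENSUS))
  hits <- scan_sequences(pwm, g$sequence, p_threshold = 1e-4)
  top <- hits[hits$p == min(hits$p), ]
  expect_setequal(unique(top$start), c(984, 7321))
  expect_setequal(top$strand[top$start == 984], c("+", "-"))
  expect_true(all(top$end - top$start + 1 == 16))
  expect_true(all(hits$q >= hits$p))
  # collapse flag keeps one strand record per palindromic locus
  collapsed <- scan_sequences(pwm, g$sequence, p_threshold = 1e-4,
                              collapse_palindromic = TRUE)
  expect_false(any(duplicated(collapsed[, c("seqid", "start", "end")])))
})

test_that("a p threshold of 1 emits every window on both strands", {
  set.seed(3)
  seqs <- c(a = random_dna(200), b = random_dna(57))
  pwm <- make_random_pwm(9, seed = 1)
  hits <- scan_sequences(pwm, seqs, p_threshold = 1)
  expect_equal(nrow(hits), 2 * sum(nchar(seqs) - 9 + 1))
})

test_that("false-positive counts follow the exact p-values", {
  # scan background-only genomes at a moderate threshold: the hit count
  # should match 2 * windows * p within Poisson fluctuation
  pwm <- make_random_pwm(10, seed = 6, conc = 0.4)
  thr <- 1e-4
  counts <- vapply(1:5, function(s) {
    g <- gen_genome(genome_sim_config(length = 50000, gc_fraction = 0.5,
                                      seed = 100 + s))
    nrow(scan_sequences(pwm, g$sequence, p_threshold = thr,
                        background = "uniform"))
  }, 0)
  n_win <- 50000 - 10 + 1
  # the DP reports the exact p of the largest integer score <= threshold,
  # so the expected count uses that attained p, bounded above by thr
  expected <- 2 * n_win * thr
  expect_lt(abs(mean(counts) - expected),
            3 * sqrt(expected / 5) + 0.05 * expected)
})

test_that("BH adjustment matches the hand-evaluated step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  # step-up definition computed directly
  o <- order(p)
  m <- length(p)
  qs <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(q[o], pmin(qs, 1))
})

test_that("hit annotation uses gene-oriented offsets with no zero", {
  hits <- data.frame(seqid = "chr", start = c(984, 810, 1000),
                     end = c(999, 825, 1015), strand = "+",
                     score = 10, p = 1e-6, q = 1e-5,
                     site_sequence = "X")
  ann <- data.frame(gene_id = c("plusG", "minusG"), seqid = "chr",
                    start = c(1000, 300), end = c(2000, 788),
                    strand = c("+", "-"),
                    translation_start = c(1000, 788))
  out <- annotate_hits(hits, ann, max_distance = 300)
  expect_equal(out$location[out$gene == "plusG" & out$start == 984], -16)
  expect_equal(out$location[out$gene == "minusG" & out$start == 810], -37)
  expect_equal(out$location[out$gene == "plusG" & out$start == 1000], 1)
  expect_false(any(out$location == 0, na.rm = TRUE))
  # a hit inside the plus gene span is not intergenic
  expect_false(out$intergenic[out$start == 1000][1])
  expect_true(out$intergenic[out$start == 984][1])
})

test_that("annotation records must carry strand and translation start", {
  hits <- data.frame(seqid = "chr", start = 10, end = 25, strand = "+",
                     score = 1, p = 0.5, q = 0.5, site_sequence = "X")
  bad <- data.frame(gene_id = "g1", seqid = "chr", start = 1, end = 100,
                    strand = "*")
  expect_error(annotate_hits(hits, bad), "g1")
  bad2 <- data.frame(gene_id = "g2", seqid = "chr", start = 1, end = 100,
                     strand = "+", translation_start = NA)
  expect_error(annotate_hits(hits, bad2), "g2")
})

test_that("annotation files round-trip through BED and GFF3", {
  g <- gen_genome(genome_sim_config(
    length = 5000,
    genes = data.frame(id = c("gA", "gB"), strand = c("+", "-"),
                       start = c(100, 2000), end = c(900, 2900)),
    seed = 4
  ), dir = withr::local_tempdir())
  for (f in c(g$paths$gff3, g$paths$bed)) {
    ann <- read_annotation(f)
    expect_setequal(ann$gene_id, c("gA", "gB"))
    expect_equal(ann$start[ann$gene_id == "gA"], 100)
    expect_equal(ann$end[ann$gene_id == "gB"], 2900)
    expect_equal(ann$translation_start[ann$gene_id == "gB"], 2900)
  }
})
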
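test_that("selection simulation is deterministic to the byte", {
  cfg <- selection_sim_config(n_reads = 150, rounds = 2, seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen_repsa_pool(cfg, d1)
  gen_repsa_pool(cfg, d2)
  for (r in 0:2) {
    f <- sprintf("round_%d.fastq", r)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("no selection pressure leaves base composition unchanged", {
  cfg <- selection_sim_config(n_reads = 800, rounds = 6, stringency = 0,
                              planted_fraction = 0, seed = 17)
  sim <- gen_repsa_pool(cfg)
  count_bases <- function(cas) tabulate(dna_codes(paste(cas, collapse = "")),
                                        nbins = 4)
  tab <- rbind(count_bases(sim$cassettes[[1]]), count_bases(sim$cassettes[[7]]))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("strong selection enriches the planted consensus across rounds", {
  cfg <- selection_sim_config(n_reads = 1000, rounds = 6, stringency = 5,
                              planted_fraction = 0.02, seed = 11)
  sim <- gen_repsa_pool(cfg)
  frac <- vapply(0:6, function(r) {
    mean(sim$truth$has_consensus[sim$truth$round == r])
  }, 0)
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[7], frac[1])

  # gentler stringency gives gradual, strictly increasing enrichment
  cfg2 <- selection_sim_config(n_reads = 1000, rounds = 6, stringency = 0.1,
                               planted_fraction = 0.02, seed = 11)
  sim2 <- gen_repsa_pool(cfg2)
  frac2 <- vapply(0:6, function(r) {
    mean(sim2$truth$has_consensus[sim2$truth$round == r])
  }, 0)
  expect_true(all(diff(frac2) > 0))
})

test_that("read counts are conserved across selection rounds", {
  cfg <- selection_sim_config(n_reads = 123, rounds = 3, seed = 5)
  sim <- gen_repsa_pool(cfg)
  expect_true(all(lengths(sim$cassettes) == 123))
  expect_equal(nrow(sim$truth), 123 * 4)
})

test_that("planted genome sites appear verbatim at stated coordinates", {
  g <- gen_genome(genome_sim_config(
    length = 3000,
    planted_sites = data.frame(sequence = WT_CONSENSUS, position = 984,
                               strand = "+"),
    seed = 1
  ))
  expect_identical(substr(g$sequence[[1]], 984, 999), WT_CONSENSUS)
  expect_equal(g$truth$start, 984)
  expect_equal(g$truth$end, 999)
  # minus-strand plants are inserted as the reverse complement
  g2 <- gen_genome(genome_sim_config(
    length = 3000,
    planted_sites = data.frame(sequence = "AAAACCCCGGGGTTTT", position = 100,
                               strand = "-"),
    seed = 1
  ))
  expect_identical(substr(g2$sequence[[1]], 100, 115),
                   revcomp("AAAACCCCGGGGTTTT"))
})

test_that("background GC tracks the configured fraction", {
  g <- gen_genome(genome_sim_config(length = 1e5, gc_fraction = 0.69,
                                    seed = 8))
  codes <- dna_codes(g$sequence[[1]])
  gc <- mean(codes %in% 2:3)
  sd3 <- 3 * sqrt(0.69 * 0.31 / 1e5)
  expect_lt(abs(gc - 0.69), sd3)
  # empty plant list: pure background, empty truth table
  expect_equal(nrow(g$truth), 0)
})

test_that("genome generation rejects invalid plants", {
  expect_error(genome_sim_config(
    length = 100,
    planted_sites = data.frame(sequence = WT_CONSENSUS, position = 95,
                               strand = "+")), "bounds")
  expect_error(genome_sim_config(
    length = 1000,
    planted_sites = data.frame(sequence = rep(WT_CONSENSUS, 2),
                               position = c(10, 20), strand = "+")),
    "overlap")
})

test_that("sensorgram traces start at zero and expose the kobs identity", {
  cfg <- sensorgram_sim_config(noise_sd = 0)
  g <- gen_sensorgrams(cfg)
  first <- g$traces[g$traces$time_s == 0, ]
  expect_true(all(first$response == 0))

  # fitted single-exponential rate of the association phase equals kon*C+koff
  C <- 100e-9
  a <- g$traces[abs(g$traces$conc_M - C) < 1e-15 & g$traces$phase == "assoc" &
                  g$traces$time_s > 0, ]
  # Levenberg-Marquardt: plain nls cannot converge on zero-residual data
  fit <- minpack.lm::nlsLM(response ~ Req * (1 - exp(-k * time_s)), data = a,
                           start = list(Req = max(a$response), k = 0.01))
  kobs <- coef(fit)[["k"]]
  expect_equal(signif(kobs, 4), signif(cfg$kon * C + cfg$koff, 4))
})

test_that("sensorgram noise is seeded and the mean is seed-independent", {
  a <- gen_sensorgrams(sensorgram_sim_config(noise_sd = 0, seed = 1))
  b <- gen_sensorgrams(sensorgram_sim_config(noise_sd = 0, seed = 2))
  expect_identical(a$traces$response, b$traces$response)
  n1 <- gen_sensorgrams(sensorgram_sim_config(noise_sd = 0.01, seed = 1))
  n2 <- gen_sensorgrams(sensorgram_sim_config(noise_sd = 0.01, seed = 2))
  expect_false(identical(n1$traces$response, n2$traces$response))
  expect_equal(mean(n1$traces$response - a$traces$response), 0,
               tolerance = 1e-3)
})

test_that("expression simulation plants effects of the stated size", {
  cfg <- expression_sim_config(residual_sd = 0.2, seed = 6)
  e <- gen_expression(cfg)
  est <- rowMeans(e$values[, 4:6]) - rowMeans(e$values[, 1:3])
  expect_lt(abs(est[["gene00001"]] - (-8.51)), 1)
  expect_lt(abs(est[["gene00002"]] - 1.95), 1)
  expect_equal(e$truth$true_logfc[e$truth$gene == "gene00003"], 1.83)
  expect_equal(sum(e$truth$true_logfc != 0), 3)
  # reproducible
  e2 <- gen_expression(cfg)
  expect_identical(e$values, e2$values)
})

test_that("a null expression simulation is calibrated", {
  hits <- vapply(1:20, function(s) {
    e <- gen_expression(expression_sim_config(
      n_genes = 200, planted_effects = numeric(0), seed = 100 + s))
    fit <- fit_two_group(e$values, e$groups)
    eb <- eb_moderate(fit, d0 = 0)   # plain t: exact null calibration
    mean(eb$table$p < 0.05)
  }, 0)
  expect_lt(abs(mean(hits) - 0.05), 0.015)
})

test_that("EMSA titrations follow the binding isotherm", {
  kd <- 65e-9
  tt <- gen_emsa_titration(kd, c(13, 26, 52, 104, 208, 415, 830) * 1e-9)
  expect_equal(tt$fraction_bound[1], 13e-9 / (13e-9 + kd))
  expect_true(all(diff(tt$fraction_bound) > 0))
  expect_equal(gen_emsa_titration(kd, kd)$fraction_bound, 0.5)
  expect_lt(gen_emsa_titration(kd, 1e-12)$fraction_bound, 1e-4)
  noisy <- gen_emsa_titration(kd, c(1e-9, 1e-6), noise_sd = 10, seed = 1)
  expect_true(all(noisy$fraction_bound >= 0 & noisy$fraction_bound <= 1))
})
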
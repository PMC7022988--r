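test_that("two-group summaries match closed forms and are antisymmetric", {
  m <- rbind(g1 = c(1, 1, 1, 2, 2, 2),
             g2 = c(3, 4, 5, 3, 4, 5))
  groups <- rep(c("reference", "perturbed"), each = 3)
  fit <- fit_two_group(m, groups)
  expect_equal(fit$logFC[fit$gene == "g1"], 1)
  expect_equal(fit$s2[fit$gene == "g1"], 0)
  expect_equal(fit$df, c(4, 4))
  expect_equal(fit$stdev_unscaled, rep(sqrt(2 / 3), 2))

  swapped <- fit_two_group(m, rev(groups))
  expect_equal(swapped$logFC, -fit$logFC)
  expect_equal(swapped$s2, fit$s2)
})

test_that("d0 = 0 reduces the moderated t to the ordinary pooled t", {
  e <- gen_expression(expression_sim_config(n_genes = 200, seed = 5))
  fit <- fit_two_group(e$values, e$groups)
  eb <- eb_moderate(fit, d0 = 0)
  ordinary <- fit$logFC / (sqrt(fit$s2) * fit$stdev_unscaled)
  expect_identical(eb$table$t, ordinary)
  expect_identical(eb$table$s2_post, fit$s2)
})

test_that("identical sample variances are a fixed point of moderation", {
  # residuals identical for every gene => identical s2
  base <- c(0, 1, 2, 5, 6, 7)
  m <- t(vapply(1:50, function(g) base + g, numeric(6)))
  rownames(m) <- sprintf("g%02d", 1:50)
  fit <- fit_two_group(m, rep(c("reference", "perturbed"), each = 3))
  expect_equal(stats::sd(fit$s2), 0)
  eb <- eb_moderate(fit)
  expect_true(is.infinite(eb$d0))
  expect_equal(eb$table$s2_post, fit$s2)
})

test_that("moderated statistics agree with the limma implementation", {
  skip_if_not_installed("limma")
  e <- gen_expression(expression_sim_config(seed = 3))
  de <- de_analyze(e$values, e$groups)
  design <- cbind(intercept = 1, pert = as.numeric(e$groups == "perturbed"))
  lf <- limma::eBayes(limma::lmFit(e$values, design))
  tt <- limma::topTable(lf, coef = 2, number = Inf, sort.by = "none")
  expect_equal(de$logFC, tt$logFC, tolerance = 1e-12)
  expect_equal(de$t, tt$t, tolerance = 1e-10)
  expect_equal(de$P.Value, tt$P.Value, tolerance = 1e-10)
  expect_equal(de$adj.P.Val, tt$adj.P.Val, tolerance = 1e-10)
  expect_equal(attr(de, "d0"), lf$df.prior, tolerance = 1e-8)
  expect_equal(attr(de, "s02"), lf$s2.prior, tolerance = 1e-8)
  # B uses the same kernel; the prior-variance estimate differs in detail
  expect_equal(de$B, tt$B, tolerance = 0.2)
})

test_that("B log-odds is minimized at t = 0 and increasing in |t|", {
  su <- rep(sqrt(2 / 3), 7)
  df <- rep(20, 7)
  t <- c(-6, -3, -1, 0, 1, 3, 6)
  B <- b_statistic(t, su, df, prior_prop = 0.01, v0 = 2)
  expect_equal(which.min(B), 4L)
  expect_true(all(diff(B[4:7]) > 0))
  expect_equal(B[1:3], rev(B[5:7]))   # symmetric in t
})

test_that("planted effects dominate the DE ranking", {
  e <- gen_expression(expression_sim_config(seed = 11))
  de <- de_analyze(e$values, e$groups)
  top <- de_toptable(de)
  expect_setequal(top$gene[1:3], c("gene00001", "gene00002", "gene00003"))
  expect_equal(top$logFC[top$gene == "gene00001"], -8.51, tolerance = 0.1)
  # the strongest planted effect carries the largest B
  expect_identical(de$gene[which.max(de$B)], "gene00001")
})

test_that("null p-values are uniform", {
  e <- gen_expression(expression_sim_config(planted_effects = numeric(0),
                                            seed = 21))
  de <- de_analyze(e$values, e$groups)
  ks <- suppressWarnings(stats::ks.test(de$P.Value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("small gene sets warn about unstable moderation", {
  e <- gen_expression(expression_sim_config(n_genes = 5,
                                            planted_effects = numeric(0),
                                            seed = 2))
  fit <- fit_two_group(e$values, e$groups)
  expect_warning(eb_moderate(fit), "unstable")
})

test_that("fold changes match the reported conversions", {
  fc <- fold_change(c(-8.51, 1.95, 0))
  expect_equal(round(fc$fold[1]), 365)
  expect_equal(signif(fc$fold[2], 2), 3.9)
  expect_identical(fc$direction, c("down", "up", "none"))
})
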
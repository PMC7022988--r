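#' Two-group per-gene summaries on log2 intensities
#'
#' For each gene: `logFC = mean(perturbed) - mean(reference)`, the pooled
#' residual variance `s2`, and residual degrees of freedom `df = n1 + n2 - 2`.
#'
#' @param values numeric matrix, genes x samples, log2 scale. Row names are
#'   gene ids.
#' @param groups character/factor of length `ncol(values)` with levels
#'   `"reference"` and `"perturbed"`.
#' @return data.frame `gene`, `logFC`, `s2`, `df`, `stdev_unscaled`
#'   (`sqrt(1/n1 + 1/n2)`). Genes with missing values are dropped with a
#'   message.
#' @export
fit_two_group <- function(values, groups) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    stop("groups must have one label per sample column")
  }
  if (!all(groups %in% c("reference", "perturbed"))) {
    stop("groups must be 'reference' or 'perturbed'")
  }
  n1 <- sum(groups == "reference")
  n2 <- sum(groups == "perturbed")
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  has_na <- rowSums(is.na(values)) > 0
  if (any(has_na)) {
    message("dropping ", sum(has_na), " gene(s) with missing values")
    values <- values[!has_na, , drop = FALSE]
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("gene%05d", seq_len(nrow(values)))
  }
  ref <- values[, groups == "reference", drop = FALSE]
  per <- values[, groups == "perturbed", drop = FALSE]
  m1 <- rowMeans(ref)
  m2 <- rowMeans(per)
  ss <- rowSums((ref - m1)^2) + rowSums((per - m2)^2)
  df <- n1 + n2 - 2
  data.frame(
    gene = rownames(values),
    logFC = m2 - m1,
    s2 = ss / df,
    df = df,
    stdev_unscaled = sqrt(1 / n1 + 1 / n2),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Newton inversion of the trigamma function (vectorized), used by the
# moment-matching estimate of the prior degrees of freedom.
trigamma_inverse <- function(x) {
  out <- x
  big <- x > 1e7
  out[big] <- 1 / sqrt(x[big])
  small <- x < 1e-6
  out[small] <- 1 / x[small]
  mid <- !(big | small)
  if (any(mid)) {
    y <- 0.5 + 1 / x[mid]
    for (i in 1:75) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2)
      y <- y + dif
      if (max(-dif / y) < 1e-10) break
    }
    out[mid] <- y
  }
  out
}

#' Empirical-Bayes variance moderation and moderated t
#'
#' Shrinks per-gene variances toward a pooled prior estimated by moment
#' matching on `log(s2)`: with `e = log(s2) - digamma(df/2) + log(df/2)`, the
#' prior degrees of freedom `d0` solve `trigamma(d0/2) = var(e) -
#' trigamma(df/2)` and the prior variance is `s0^2 = exp(mean(e) +
#' digamma(d0/2) - log(d0/2))`. The posterior variance is
#' `s_tilde^2 = (d0*s0^2 + df*s2) / (d0 + df)` and the moderated t is
#' `logFC / (s_tilde * stdev_unscaled)` on `d0 + df` degrees of freedom.
#' When the moment estimate diverges (no excess spread in the observed
#' variances) `d0` is set to infinity and `s0^2` to the mean observed
#' variance, so identical sample variances are a fixed point.
#'
#' @param fit data.frame from [fit_two_group()].
#' @param d0 optional forced prior degrees of freedom (0 turns moderation off
#'   and recovers the ordinary pooled t exactly).
#' @return list with `d0`, `s02`, and a data.frame `table` adding `s2_post`,
#'   `t`, `df_total`, `p` to the fit columns.
#' @export
eb_moderate <- function(fit, d0 = NULL) {
  s2 <- fit$s2
  df <- fit$df
  if (length(s2) < 10) {
    warning("fewer than 10 genes: prior degrees of freedom are unstable")
  }
  if (is.null(d0)) {
    pos <- s2 > 0
    if (!any(pos)) {
      d0 <- Inf
      s02 <- mean(s2)
    } else {
      z <- log(s2[pos])
      e <- z - digamma(df[pos] / 2) + log(df[pos] / 2)
      evar <- stats::var(e) - mean(trigamma(df[pos] / 2))
      if (is.na(evar) || evar <= 0) {
        d0 <- Inf
        s02 <- mean(s2)
      } else {
        d0 <- 2 * trigamma_inverse(evar)
        s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      }
    }
  } else {
    s02 <- if (d0 > 0) mean(s2) else NA_real_
  }
  if (d0 == 0) {
    s2_post <- s2
  } else if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
  } else {
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
  }
  df_total <- df + d0
  tstat <- fit$logFC / (sqrt(s2_post) * fit$stdev_unscaled)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  tab <- cbind(fit, data.frame(s2_post = s2_post, t = tstat,
                               df_total = df_total, p = p))
  list(d0 = d0, s02 = s02, table = tab)
}

# limma-style estimate of the prior variance of true effects among DE genes,
# from the most extreme moderated t statistics.
estimate_v0 <- function(tstat, stdev_unscaled, df_total, prior_prop) {
  ngenes <- length(tstat)
  ntarget <- ceiling(prior_prop / 2 * ngenes)
  if (ntarget < 1) return(stdev_unscaled[1]^2)
  p <- max(ntarget / ngenes, prior_prop)
  at <- abs(tstat)
  maxdf <- max(df_total)
  o <- order(at, decreasing = TRUE)[seq_len(ntarget)]
  t1 <- at[o]
  v1 <- stdev_unscaled[o]^2
  r <- seq_len(ntarget)
  p0 <- 2 * stats::pt(-t1, df = maxdf)
  ptarget <- ((r - 0.5) / ngenes - (1 - p) * p0) / p
  v0 <- numeric(ntarget)
  pos <- ptarget > p0
  if (any(pos)) {
    qtarget <- stats::qt(ptarget[pos] / 2, df = maxdf)
    v0[pos] <- v1[pos] * ((t1[pos] / qtarget)^2 - 1)
  }
  mean(pmax(v0, 0))
}

#' Log-odds (B statistic) of differential expression
#'
#' Posterior log-odds that a gene is differentially expressed under the
#' moderated-t model, given a prior proportion `prior_prop` of DE genes and a
#' prior variance `v0` for true effects (estimated from the extreme t
#' statistics when not supplied). Minimized at t = 0 and strictly increasing
#' in |t|.
#'
#' @param tstat moderated t statistics.
#' @param stdev_unscaled per-gene unscaled coefficient standard deviations.
#' @param df_total total (prior + residual) degrees of freedom per gene.
#' @param prior_prop prior proportion of DE genes.
#' @param v0 optional prior variance of true effects (unscaled units).
#' @return numeric vector of B values.
#' @export
b_statistic <- function(tstat, stdev_unscaled, df_total, prior_prop = 0.01,
                        v0 = NULL) {
  if (is.null(v0)) {
    v0 <- estimate_v0(tstat, stdev_unscaled, df_total, prior_prop)
  }
  if (v0 <= 0) v0 <- max(stdev_unscaled^2)
  r <- (stdev_unscaled^2 + v0) / stdev_unscaled^2
  t2 <- tstat^2
  kernel <- ifelse(is.finite(df_total),
                   (1 + df_total) / 2 * log((t2 + df_total) /
                                              (t2 / r + df_total)),
                   t2 * (1 - 1 / r) / 2)
  log(prior_prop / (1 - prior_prop)) - log(r) / 2 + kernel
}

#' Two-group moderated-t differential expression
#'
#' Full pipeline step on a log2 expression matrix: per-gene fold changes,
#' empirical-Bayes moderated t statistics, two-sided p-values,
#' Benjamini-Hochberg adjusted p-values (via the shared [bh_adjust()]), and B
#' log-odds.
#'
#' @param values genes x samples log2 matrix (or TSV path: first column gene
#'   ids, remaining columns samples).
#' @param groups sample group labels (`"reference"`/`"perturbed"`), or the
#'   path of a two-column TSV (sample, group).
#' @param prior_prop prior proportion of DE genes for the B statistic.
#' @param d0 optional forced prior degrees of freedom (see [eb_moderate()]).
#' @return a `de_result` data.frame: `gene`, `logFC`, `t`, `P.Value`,
#'   `adj.P.Val`, `B`, in input gene order, with attributes `d0`, `s02`.
#' @export
de_analyze <- function(values, groups, prior_prop = 0.01, d0 = NULL) {
  if (is.character(values) && length(values) == 1L) {
    tab <- utils::read.delim(values, check.names = FALSE)
    values <- as.matrix(tab[, -1, drop = FALSE])
    rownames(values) <- tab[[1]]
  }
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    gt <- utils::read.delim(groups, header = TRUE)
    groups <- gt[[2]][match(colnames(values), gt[[1]])]
  }
  fit <- fit_two_group(values, groups)
  eb <- eb_moderate(fit, d0 = d0)
  tab <- eb$table
  B <- b_statistic(tab$t, tab$stdev_unscaled, tab$df_total, prior_prop)
  out <- data.frame(
    gene = tab$gene, logFC = tab$logFC, t = tab$t, P.Value = tab$p,
    adj.P.Val = bh_adjust(tab$p), B = B, stringsAsFactors = FALSE
  )
  attr(out, "d0") <- eb$d0
  attr(out, "s02") <- eb$s02
  class(out) <- c("de_result", "data.frame")
  out
}

#' Rank a DE table the way the source tables are ordered
#'
#' Stable deterministic ordering by adjusted p, then raw p, then gene id.
#'
#' @param de a `de_result` from [de_analyze()].
#' @return the reordered data.frame.
#' @export
de_toptable <- function(de) {
  de[order(de$adj.P.Val, de$P.Value, de$gene), , drop = FALSE]
}

#' Linear fold change from a log2 fold change
#'
#' @param logfc log2 fold change(s).
#' @return data.frame with `fold` (`2^|logFC|`, always >= 1) and `direction`
#'   (`"up"`, `"down"`, or `"none"` at exactly 0).
#' @export
fold_change <- function(logfc) {
  data.frame(
    fold = 2^abs(logfc),
    direction = ifelse(logfc > 0, "up", ifelse(logfc < 0, "down", "none")),
    stringsAsFactors = FALSE
  )
}
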
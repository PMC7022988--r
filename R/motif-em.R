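# Window-indexing machinery shared by the EM and by the selection simulator.
#
# For N equal-length cassettes and motif width w there are K = 2 * (L - w + 1)
# candidate site placements per cassette (every window on both strands).
# `window_index()` returns an N x K x w integer array of base codes, so that
# any per-window log score is a single lookup-and-sum over the last margin.
window_index <- function(cassettes, width) {
  L <- unique(nchar(cassettes))
  if (length(L) != 1L) stop("cassettes must share one length")
  if (width > L) stop("motif width exceeds cassette length")
  n <- length(cassettes)
  npos <- L - width + 1L
  codes <- matrix(dna_codes(paste(cassettes, collapse = "")),
                  nrow = n, byrow = TRUE)
  if (anyNA(codes)) stop("cassettes must contain only A/C/G/T")
  rccodes <- (5L - codes)[, rev(seq_len(L)), drop = FALSE]
  idx <- array(0L, dim = c(n, 2L * npos, width))
  for (k in seq_len(npos)) {
    idx[, k, ] <- codes[, k:(k + width - 1L), drop = FALSE]
    idx[, npos + k, ] <- rccodes[, k:(k + width - 1L), drop = FALSE]
  }
  idx
}

# per-window sums of a position x base log matrix over a window_index() array
window_scores <- function(idx, logmat) {
  d <- dim(idx)
  flat <- matrix(0, nrow = d[1] * d[2], ncol = d[3])
  for (i in seq_len(d[3])) {
    flat[, i] <- logmat[i, as.vector(idx[, , i])]
  }
  matrix(rowSums(flat), nrow = d[1], ncol = d[2])
}

# best-window log2-odds of each cassette under a PWM (both strands)
best_window_logodds <- function(cassettes, pwm) {
  idx <- window_index(cassettes, pwm_width(pwm))
  lo <- t(log2(pwm$prob) - rep(log2(pwm$background), each = pwm_width(pwm)))
  # lo is base x position; window_scores wants position x base
  s <- window_scores(idx, t(lo))
  apply(s, 1, max)
}

#' EM motif discovery on a cassette pool
#'
#' Fits a fixed-width motif to a pool of equal-length cassettes by
#' expectation-maximization over site placements on both strands, under either
#' the OOPS (one occurrence per sequence) or ZOOPS (zero or one occurrence)
#' model. With `palindromic = TRUE` the expected site counts are symmetrized
#' with their reverse complement in every M-step, which is the maximum-
#' likelihood update under the constraint that the motif equal its own
#' reverse complement (homodimer-type sites).
#'
#' The best of `n_starts` random restarts (seeded from cassette windows,
#' sharpened to 0.7 on the observed base) is returned. Within each restart the
#' log-likelihood is non-decreasing.
#'
#' @param pool a `cassette_pool` from [extract_cassettes()], or a character
#'   vector of equal-length A/C/G/T cassettes.
#' @param width motif width in bases (must not exceed the cassette length).
#' @param model `"zoops"` (default) or `"oops"`.
#' @param palindromic constrain the motif to reverse-complement symmetry.
#' @param n_starts number of random restarts.
#' @param tol absolute log-likelihood change declaring convergence.
#' @param max_iter iteration cap per restart.
#' @param pseudocount per-base pseudocount added in each M-step.
#' @param seed optional integer seed for the restarts.
#' @return a `motif_result` list: `pwm`, `n_sites`, `log_likelihood`,
#'   `significance` (likelihood-ratio diagnostic, not comparable to MEME
#'   E-values), `consensus`, `ic`, `site_prior`, `ll_trace`, `converged`.
#' @export
em_fit <- function(pool, width, model = c("zoops", "oops"),
                   palindromic = FALSE, n_starts = 10, tol = 1e-6,
                   max_iter = 500, pseudocount = 0.25, seed = NULL) {
  model <- match.arg(model)
  cassettes <- if (inherits(pool, "cassette_pool")) pool$cassettes else pool
  if (length(cassettes) == 0L) stop("empty cassette pool")
  L <- unique(nchar(cassettes))
  if (length(L) != 1L) stop("cassettes must share one length")
  if (width > L) stop("motif width exceeds cassette length")
  if (!is.null(seed)) set.seed(seed)

  n <- length(cassettes)
  idx <- window_index(cassettes, width)
  K <- dim(idx)[2]

  # 0-order background from the pool, symmetrized over strands
  counts <- tabulate(as.vector(idx[, seq_len(K / 2), 1]), nbins = 4)
  allcounts <- tabulate(dna_codes(paste(cassettes, collapse = "")), nbins = 4)
  bg <- (allcounts + allcounts[COMP_IDX]) / (2 * sum(allcounts))
  log_bg <- log(bg)

  # background log-probability of each window and of each full cassette
  bg_win <- window_scores(idx, matrix(rep(log_bg, each = width), nrow = width))
  codes_full <- matrix(dna_codes(paste(cassettes, collapse = "")),
                       nrow = n, byrow = TRUE)
  bg_full <- rowSums(matrix(log_bg[codes_full], nrow = n))

  one_d <- dim(idx)
  flat_idx <- matrix(0L, nrow = one_d[1] * one_d[2], ncol = one_d[3])
  for (i in seq_len(one_d[3])) flat_idx[, i] <- as.vector(idx[, , i])

  run_once <- function(pwm0) {
    logp <- log(pwm0)
    gamma <- if (model == "zoops") 0.5 else 1
    ll_old <- -Inf
    ll_trace <- numeric(0)
    z <- NULL
    converged <- FALSE
    pwm_cur <- pwm0
    for (iter in seq_len(max_iter)) {
      # E-step: posterior over placements (and absence, for ZOOPS)
      s <- window_scores(idx, logp) - bg_win       # log odds per window
      m <- apply(s, 1, max)
      es <- exp(s - m)
      rs <- rowSums(es)
      if (model == "zoops") {
        w0 <- (1 - gamma) * exp(-m)                # relative weight of "no site"
        denom <- w0 + (gamma / K) * rs
        z <- es * (gamma / K) / denom
        ll <- sum(bg_full + m + log(denom))
      } else {
        z <- es / rs
        ll <- sum(bg_full + m + log(rs / K))
      }
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
      # M-step: expected base counts per motif position
      zv <- as.vector(z)
      cnt <- matrix(0, nrow = width, ncol = 4)
      for (i in seq_len(width)) {
        cnt[i, ] <- vapply(1:4, function(b) sum(zv[flat_idx[, i] == b]), 0)
      }
      if (palindromic) {
        cnt <- (cnt + cnt[rev(seq_len(width)), COMP_IDX, drop = FALSE]) / 2
      }
      cnt <- cnt + pseudocount
      pwm_cur <- cnt / rowSums(cnt)
      logp <- log(pwm_cur)
      if (model == "zoops") {
        gamma <- min(max(mean(rowSums(z)), 1e-4), 1 - 1e-4)
      }
    }
    list(pwm = pwm_cur, gamma = gamma, ll = ll_trace[length(ll_trace)],
         ll_trace = ll_trace, z = z, converged = converged)
  }

  starts <- lapply(seq_len(n_starts), function(s) {
    j <- sample.int(n, 1)
    k <- sample.int(L - width + 1L, 1)
    seqcodes <- dna_codes(substr(cassettes[j], k, k + width - 1L))
    p0 <- matrix(0.1, nrow = width, ncol = 4)
    p0[cbind(seq_len(width), seqcodes)] <- 0.7
    if (palindromic) {
      p0 <- (p0 + p0[rev(seq_len(width)), COMP_IDX, drop = FALSE]) / 2
    }
    p0
  })
  runs <- lapply(starts, run_once)
  best <- runs[[which.max(vapply(runs, `[[`, 0, "ll"))]]

  pwm <- new_pwm(best$pwm, background = bg, pseudocount = pseudocount)
  n_sites <- round(sum(rowSums(best$z)))
  # likelihood-ratio diagnostic vs the pure-background model; Bonferroni-style
  # scaling by the number of candidate placements. A rough indicator only.
  ll0 <- sum(bg_full)
  lr_p <- stats::pchisq(2 * (best$ll - ll0), df = 3 * width + 1,
                        lower.tail = FALSE)
  significance <- min(lr_p * n * K, .Machine$double.xmax)
  structure(list(
    pwm = pwm,
    n_sites = n_sites,
    log_likelihood = best$ll,
    significance = significance,
    consensus = consensus_string(pwm),
    ic = information_content(pwm),
    site_prior = best$gamma,
    ll_trace = best$ll_trace,
    converged = best$converged,
    model = model,
    palindromic = palindromic
  ), class = "motif_result")
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf("motif_result: width %d, %s%s, %d sites, logL %.2f\n",
              pwm_width(x$pwm), x$model,
              if (x$palindromic) " (palindromic)" else "",
              x$n_sites, x$log_likelihood))
  cat("consensus:", x$consensus, "\n")
  cat("top bases:", pwm_top_string(x$pwm), "\n")
  invisible(x)
}
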
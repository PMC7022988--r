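#' 1:1 Langmuir association-then-dissociation response
#'
#' Single-state binding of an analyte at concentration `C` to an immobilized
#' ligand. During association (`t <= t_assoc`):
#' `R(t) = Req * (1 - exp(-kobs * t))` with `kobs = kon * C + koff` and
#' `Req = Rmax * C / (C + KD)`, `KD = koff / kon`. During dissociation:
#' `R(t) = R(t_assoc) * exp(-koff * (t - t_assoc))`. Continuous at `t_assoc`.
#'
#' @param kon association rate constant (1/(M*s)).
#' @param koff dissociation rate constant (1/s).
#' @param Rmax maximal response (response units).
#' @param C analyte concentration (M).
#' @param t time(s) in seconds, >= 0.
#' @param t_assoc association/dissociation boundary (s).
#' @return response at each `t`.
#' @export
model_response <- function(kon, koff, Rmax, C, t, t_assoc) {
  stopifnot(kon > 0, koff > 0, Rmax > 0, C > 0, t_assoc > 0)
  if (any(t < 0)) stop("t must be >= 0")
  kobs <- kon * C + koff
  Req <- Rmax * C / (C + koff / kon)
  r_assoc_end <- Req * (1 - exp(-kobs * t_assoc))
  ifelse(t <= t_assoc,
         Req * (1 - exp(-kobs * t)),
         r_assoc_end * exp(-koff * (t - t_assoc)))
}

#' Equilibrium dissociation constant from rate constants
#' @param kon association rate constant (1/(M*s)).
#' @param koff dissociation rate constant (1/s).
#' @return `KD = koff / kon` (M).
#' @export
compute_kd <- function(kon, koff) koff / kon

#' Classify a binding affinity by its KD
#'
#' Default bands: high < 1 nM <= intermediate < 100 nM <= weak < 10 uM <=
#' nonspecific.
#'
#' @param kd dissociation constant(s), molar.
#' @param thresholds named molar cutoffs `c(high=, intermediate=, weak=)`.
#' @return character vector of class labels.
#' @export
classify_affinity <- function(kd, thresholds = c(high = 1e-9,
                                                 intermediate = 1e-7,
                                                 weak = 1e-5)) {
  th <- thresholds
  ifelse(kd < th[["high"]], "high",
         ifelse(kd < th[["intermediate"]], "intermediate",
                ifelse(kd < th[["weak"]], "weak", "nonspecific")))
}

# normalize trace input to a data.frame(time_s, response, conc_M) + t_assoc
prepare_traces <- function(traces, t_assoc = NULL) {
  if (is.character(traces)) {
    traces <- do.call(rbind, lapply(traces, utils::read.csv))
  }
  traces <- as.data.frame(traces)
  req <- c("time_s", "response", "conc_M")
  if (!all(req %in% names(traces))) {
    stop("traces need columns time_s, response, conc_M")
  }
  if (is.null(t_assoc)) {
    if (!"phase" %in% names(traces)) {
      stop("supply t_assoc or a phase column (assoc/dissoc)")
    }
    # boundary between the last association and first dissociation samples
    t_assoc <- (max(traces$time_s[traces$phase == "assoc"]) +
                  min(traces$time_s[traces$phase == "dissoc"])) / 2
  }
  list(df = traces, t_assoc = t_assoc)
}

#' Global 1:1 kinetic fit of a sensorgram set
#'
#' Fits one shared (kon, koff, Rmax) triple across all concentration traces by
#' Levenberg-Marquardt least squares on log-parameterized rates (positivity by
#' construction). Initial values come from a linearized kobs-versus-C
#' regression on the association phases. The global R^2 is computed over the
#' concatenated association + dissociation points of all traces.
#'
#' @param traces data.frame with columns `time_s`, `response`, `conc_M`, and
#'   optionally `phase` (`"assoc"`/`"dissoc"`), or CSV path(s) with those
#'   columns.
#' @param t_assoc association/dissociation boundary (s); inferred from the
#'   `phase` column when absent.
#' @param init optional named list/vector with starting `kon`, `koff`, `Rmax`.
#' @return a `kinetic_fit`: `kon`, `koff`, `Rmax`, `KD` (= koff/kon), `r2`,
#'   `converged`, `n_traces`, `t_assoc`, per-trace residual standard
#'   deviations, and the fitted object's diagnostics.
#' @export
fit_global <- function(traces, t_assoc = NULL, init = NULL) {
  pt <- prepare_traces(traces, t_assoc)
  df <- pt$df
  t_assoc <- pt$t_assoc
  concs <- sort(unique(df$conc_M))
  if (any(concs <= 0)) stop("concentrations must be positive")
  if (length(concs) < 2) {
    warning("single-concentration fit: kon and Rmax are weakly identified")
  }

  degenerate <- stats::sd(df$response) < 1e-12 ||
    max(abs(df$response)) < 1e-12
  if (degenerate) {
    fit <- structure(list(kon = NA_real_, koff = NA_real_, Rmax = NA_real_,
                          KD = NA_real_, r2 = NA_real_, converged = FALSE,
                          message = "degenerate traces (no signal)",
                          n_traces = length(concs), t_assoc = t_assoc),
                     class = "kinetic_fit")
    return(fit)
  }

  if (is.null(init)) init <- init_kinetics(df, t_assoc, concs)
  par0 <- log(c(kon = unname(init[["kon"]]), koff = unname(init[["koff"]]),
                Rmax = unname(init[["Rmax"]])))

  resid_fun <- function(par) {
    kon <- exp(par[1]); koff <- exp(par[2]); Rmax <- exp(par[3])
    pred <- numeric(nrow(df))
    for (C in concs) {
      sel <- df$conc_M == C
      pred[sel] <- model_response(kon, koff, Rmax, C, df$time_s[sel], t_assoc)
    }
    pred - df$response
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  kon <- exp(unname(fit$par[1]))
  koff <- exp(unname(fit$par[2]))
  Rmax <- exp(unname(fit$par[3]))
  ssr <- sum(fit$fvec^2)
  sstot <- sum((df$response - mean(df$response))^2)
  r2 <- 1 - ssr / sstot
  per_trace <- vapply(concs, function(C) {
    stats::sd(fit$fvec[df$conc_M == C])
  }, 0)
  names(per_trace) <- format(concs, scientific = TRUE)
  structure(list(
    kon = kon, koff = koff, Rmax = Rmax, KD = compute_kd(kon, koff),
    r2 = r2, converged = fit$info %in% 1:4, message = fit$message,
    n_traces = length(concs), t_assoc = t_assoc,
    per_trace_resid_sd = per_trace, niter = fit$niter
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("1:1 kinetic fit",
      if (!isTRUE(x$converged)) "(NOT converged)" else "", "\n")
  cat(sprintf("  kon  = %.4g 1/(M*s)\n  koff = %.4g 1/s\n  Rmax = %.4g\n",
              x$kon, x$koff, x$Rmax))
  cat(sprintf("  KD   = %.4g M\n  R^2  = %.4f over %d trace(s)\n",
              x$KD, x$r2, x$n_traces))
  invisible(x)
}

# Linearized starting values: per-trace kobs from the association phase via
# log(Rend - R) regression, then kobs = kon*C + koff by ordinary regression.
init_kinetics <- function(df, t_assoc, concs) {
  kobs <- vapply(concs, function(C) {
    a <- df[df$conc_M == C & df$time_s <= t_assoc & df$time_s > 0, ]
    a <- a[order(a$time_s), ]
    n <- nrow(a)
    rend <- mean(a$response[max(1, n - 4):n])
    use <- a$response < 0.95 * rend & a$response > 0 & a$time_s > 0
    if (sum(use) < 3 || rend <= 0) return(NA_real_)
    y <- log(pmax(rend - a$response[use], 1e-12 * abs(rend)))
    -stats::coef(stats::lm(y ~ a$time_s[use]))[[2]]
  }, 0)
  ok <- is.finite(kobs) & kobs > 0
  kon <- 1e5; koff <- 1e-3
  if (sum(ok) >= 2) {
    co <- stats::coef(stats::lm(kobs[ok] ~ concs[ok]))
    if (co[[2]] > 0) kon <- co[[2]]
    if (co[[1]] > 0) koff <- co[[1]]
  }
  # refine koff from the pooled dissociation decay when available
  d <- df[df$time_s > t_assoc & df$response > 0, ]
  if (nrow(d) > 10) {
    dd <- d[d$conc_M == max(d$conc_M), ]
    if (nrow(dd) > 5) {
      sl <- -stats::coef(stats::lm(log(dd$response) ~ dd$time_s))[[2]]
      if (is.finite(sl) && sl > 0) koff <- sl
    }
  }
  kd <- koff / kon
  cmax <- max(concs)
  rmax <- max(df$response) * (cmax + kd) / cmax
  if (!is.finite(rmax) || rmax <= 0) rmax <- max(abs(df$response))
  c(kon = kon, koff = koff, Rmax = rmax)
}

#' Equilibrium KD from an EMSA titration
#'
#' Two estimators of the equilibrium dissociation constant from fraction-bound
#' measurements `theta(C) = C / (C + KD)`:
#' the midpoint method interpolates log-linearly in concentration to the
#' protein concentration at which half the probe is bound, and the
#' least-squares method fits the binding isotherm directly.
#'
#' @param titration data.frame with columns `conc_M` and `fraction_bound`.
#' @param method `"both"` (default), `"midpoint"`, or `"least-squares"`. With
#'   `"both"`, a titration that never brackets theta = 0.5 yields `NA` for the
#'   midpoint (with a warning) while the least-squares estimate is still
#'   returned, flagged extrapolated; with `"midpoint"` it is an error.
#' @return an `equilibrium_fit`: `kd_midpoint`, `kd_ls`, `extrapolated`,
#'   `method`.
#' @export
fit_emsa <- function(titration, method = c("both", "midpoint",
                                           "least-squares")) {
  method <- match.arg(method)
  df <- as.data.frame(titration)
  if (!all(c("conc_M", "fraction_bound") %in% names(df))) {
    stop("titration needs columns conc_M, fraction_bound")
  }
  df <- df[order(df$conc_M), ]
  extrapolated <- all(df$fraction_bound < 0.5) || all(df$fraction_bound > 0.5)

  midpoint <- function() {
    th <- df$fraction_bound
    exact <- which(th == 0.5)
    if (length(exact)) return(df$conc_M[exact[1]])
    below <- which(th < 0.5)
    above <- which(th > 0.5)
    if (!length(below) || !length(above) || max(below) > min(above)) {
      stop("titration does not bracket fraction bound = 0.5")
    }
    i <- max(below[below < min(above)]); j <- min(above)
    lc <- log(df$conc_M)
    exp(lc[i] + (0.5 - th[i]) / (th[j] - th[i]) * (lc[j] - lc[i]))
  }
  kd_mid <- NA_real_
  if (method %in% c("both", "midpoint")) {
    if (method == "midpoint") {
      kd_mid <- midpoint()
    } else {
      kd_mid <- tryCatch(midpoint(), error = function(e) {
        warning(conditionMessage(e)); NA_real_
      })
    }
  }
  kd_ls <- NA_real_
  if (method %in% c("both", "least-squares")) {
    ss <- function(logkd) {
      kd <- exp(logkd)
      sum((df$fraction_bound - df$conc_M / (df$conc_M + kd))^2)
    }
    lo <- log(min(df$conc_M)) - 12
    hi <- log(max(df$conc_M)) + 12
    kd_ls <- exp(stats::optimize(ss, c(lo, hi), tol = 1e-12)$minimum)
  }
  structure(list(kd_midpoint = kd_mid, kd_ls = kd_ls,
                 extrapolated = extrapolated, method = method,
                 n = nrow(df)),
            class = "equilibrium_fit")
}

#' @export
print.equilibrium_fit <- function(x, ...) {
  cat(sprintf("EMSA equilibrium fit (n = %d)%s\n", x$n,
              if (x$extrapolated) " [extrapolated]" else ""))
  cat(sprintf("  KD midpoint      = %.4g M\n", x$kd_midpoint))
  cat(sprintf("  KD least-squares = %.4g M\n", x$kd_ls))
  invisible(x)
}
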
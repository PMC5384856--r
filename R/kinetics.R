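# Pump-probe kinetic models. Time in ps, absorbance change in mOD.
#
#   mono_decay_offset: A  exp(-t/tau)   + C
#   biphasic_rise:     A1 (1-exp(-t/tau1)) + A2 (1-exp(-t/tau2))
#   decay_plus_rise:   A1 exp(-t/tau1)     + A2 (1-exp(-t/tau2))
#
# An optional Gaussian instrument response (FWHM in ps) is applied
# analytically term by term; it is off by default since the observed
# kinetics are well separated from the ~0.1 ps time resolution.

KINETIC_FORMS <- c("mono_decay_offset", "biphasic_rise", "decay_plus_rise")

# H(t) exp(-t/tau) convolved with a unit-area Gaussian of width sigma
conv_decay <- function(t, tau, sigma) {
  if (sigma <= 0) return(ifelse(t >= 0, exp(-t / tau), 0))
  arg <- (sigma / tau - t / sigma) / sqrt(2)
  0.5 * exp(sigma^2 / (2 * tau^2) - t / tau) *
    2 * stats::pnorm(arg * sqrt(2), lower.tail = FALSE)
}

conv_step <- function(t, sigma) {
  if (sigma <= 0) return(as.numeric(t >= 0))
  stats::pnorm(t / sigma)
}

#' Evaluate a kinetic model curve
#'
#' @param form One of `"mono_decay_offset"`, `"biphasic_rise"`,
#'   `"decay_plus_rise"`.
#' @param t Delays, ps.
#' @param params Named list/vector: `A`, `tau`, `C` (mono) or `A1`, `tau1`,
#'   `A2`, `tau2` (biphasic forms). All time constants must be positive.
#' @param irf_fwhm Gaussian IRF FWHM in ps; 0 disables convolution.
#' @return Numeric vector of model absorbance changes, mOD.
#' @export
kinetic_curve <- function(form, t, params, irf_fwhm = 0) {
  form <- match.arg(form, KINETIC_FORMS)
  p <- as.list(params)
  sig <- irf_fwhm / (2 * sqrt(2 * log(2)))
  taus <- unlist(p[grep("^tau", names(p))])
  if (any(taus <= 0)) stop("all time constants must be positive",
                           call. = FALSE)
  switch(form,
    mono_decay_offset =
      p$A * conv_decay(t, p$tau, sig) + p$C * conv_step(t, sig),
    biphasic_rise =
      p$A1 * (conv_step(t, sig) - conv_decay(t, p$tau1, sig)) +
      p$A2 * (conv_step(t, sig) - conv_decay(t, p$tau2, sig)),
    decay_plus_rise =
      p$A1 * conv_decay(t, p$tau1, sig) +
      p$A2 * (conv_step(t, sig) - conv_decay(t, p$tau2, sig))
  )
}

#' Simulate a pump-probe transient
#'
#' Model curve plus i.i.d. Gaussian noise at the detection noise floor
#' (0.03 mOD by default), seeded for reproducibility.
#'
#' @inheritParams kinetic_curve
#' @param delays Strictly increasing delays, ps.
#' @param noise_sigma Gaussian noise standard deviation, mOD.
#' @param seed RNG seed (required when `noise_sigma > 0`).
#' @param probe_frequency Probe frequency label, cm^-1.
#' @return Tibble of class `transient_trace` with columns `delay_ps`,
#'   `dA_mOD`; attributes `form`, `params`, `noise_sigma`,
#'   `probe_frequency`, `seed`.
#' @export
simulate_transient <- function(form, delays, params, noise_sigma = 0.03,
                               seed = NULL, probe_frequency = NA_real_,
                               irf_fwhm = 0) {
  if (is.unsorted(delays, strictly = TRUE)) {
    stop("delays must be strictly increasing", call. = FALSE)
  }
  y <- kinetic_curve(form, delays, params, irf_fwhm)
  if (noise_sigma > 0) {
    if (is.null(seed)) stop("a seed is required for noisy simulation",
                            call. = FALSE)
    set.seed(seed)
    y <- y + stats::rnorm(length(delays), 0, noise_sigma)
  }
  out <- tibble::new_tibble(tibble::tibble(delay_ps = delays, dA_mOD = y),
                            class = "transient_trace")
  attr(out, "form") <- form
  attr(out, "params") <- params
  attr(out, "noise_sigma") <- noise_sigma
  attr(out, "probe_frequency") <- probe_frequency
  attr(out, "seed") <- seed
  out
}

#' Log-spaced pump-probe delay grid
#'
#' @param from,to Range, ps.
#' @param n Number of points.
#' @return Strictly increasing numeric vector.
#' @export
log_delays <- function(from = 0.2, to = 100, n = 80) {
  exp(seq(log(from), log(to), length.out = n))
}

check_trace <- function(trace) {
  stopifnot(all(c("delay_ps", "dA_mOD") %in% names(trace)))
  if (nrow(trace) < 8) stop("at least 8 points are required for fitting",
                            call. = FALSE)
  if (is.unsorted(trace$delay_ps, strictly = TRUE)) {
    stop("delays must be strictly increasing", call. = FALSE)
  }
  invisible(trace)
}

new_kinetic_fit <- function(form, coefs, ses, sigma, converged, trace,
                            fitted, ill_conditioned = FALSE,
                            amplitudes = NULL) {
  structure(list(
    form = form,
    parameters = tibble::tibble(term = names(coefs),
                                estimate = unname(coefs),
                                std_error = unname(ses)),
    sigma = sigma, converged = converged,
    ill_conditioned = ill_conditioned,
    n = if (is.data.frame(trace)) nrow(trace) else
      sum(vapply(trace, nrow, 0L)),
    data = trace, fitted = fitted, amplitudes = amplitudes
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> form = %s, %s, residual RMS = %.4g mOD\n",
              x$form, if (x$converged) "converged" else "NOT converged",
              x$sigma))
  if (x$ill_conditioned) {
    cat("  warning: time constants within 10% of each other",
        "(ill-conditioned)\n")
  }
  print(x$parameters)
  invisible(x)
}

# tail-based automatic starting values
start_mono <- function(t, y) {
  ntail <- max(3L, ceiling(length(t) * 0.1))
  C0 <- mean(utils::tail(y, ntail))
  A0 <- y[1] - C0
  tau0 <- (max(t) - min(t)) / 3
  resid <- y - C0
  use <- which(sign(resid) == sign(A0) & abs(resid) > 0.05 * abs(A0))
  use <- use[t[use] <= stats::median(t)]
  if (length(use) >= 3 && abs(A0) > 0) {
    fitl <- stats::lm(log(abs(resid[use])) ~ t[use])
    sl <- stats::coef(fitl)[2]
    if (is.finite(sl) && sl < 0) tau0 <- min(max(-1 / sl, 1e-3), 10 * tau0)
  }
  list(A = A0, tau = tau0, C = C0)
}

# amplitudes by linear least squares given fixed time constants
start_biphasic <- function(t, y, form, tau1, tau2) {
  b1 <- if (form == "biphasic_rise") 1 - exp(-t / tau1) else exp(-t / tau1)
  b2 <- 1 - exp(-t / tau2)
  amp <- tryCatch(stats::coef(stats::lm(y ~ b1 + b2 - 1)),
                  error = function(e) c(b1 = y[length(y)] / 2,
                                        b2 = y[length(y)] / 2))
  list(A1 = unname(amp[1]), tau1 = tau1, A2 = unname(amp[2]), tau2 = tau2)
}

# Levenberg-Marquardt on the raw residuals; robust to directions that a
# full nls model matrix would reject as singular (e.g. a vanishing
# amplitude making its time constant unidentifiable).
run_nls <- function(trace, form, start, lower, irf_fwhm) {
  resid_fn <- function(p) {
    trace$dA_mOD - kinetic_curve(form, trace$delay_ps, as.list(p), irf_fwhm)
  }
  tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
}

#' Fit a mono-exponential bleach decay with offset
#'
#' Nonlinear least squares of `A exp(-t/tau) + C`. Starting values are
#' derived automatically (offset from the tail mean, decay time from a
#' log-linear regression) unless supplied. Non-convergence is flagged in
#' the result, never thrown; the residual RMS is reported either way.
#' Parameter uncertainties are 1-sigma values from the Jacobian-based
#' covariance scaled by the residual variance.
#'
#' @param trace A [simulate_transient()] trace or any tibble with
#'   `delay_ps`, `dA_mOD`.
#' @param start Optional named list of starting values (`A`, `tau`, `C`).
#' @param irf_fwhm Gaussian IRF FWHM in ps (0 = none, the default).
#' @return A `kinetic_fit` object; see [tidy.kinetic_fit()].
#' @export
fit_monoexponential <- function(trace, start = NULL, irf_fwhm = 0) {
  check_trace(trace)
  if (is.null(start)) start <- start_mono(trace$delay_ps, trace$dA_mOD)
  fit <- run_nls(trace, "mono_decay_offset", start,
                 lower = c(A = -Inf, tau = 1e-4, C = -Inf), irf_fwhm)
  finalize_fit(fit, "mono_decay_offset", start, trace, irf_fwhm)
}

#' Fit a biphasic rise (or decay-plus-rise) transient
#'
#' Nonlinear least squares of the two-component kinetics with automatic
#' starting values (fast constant ~1 ps, slow constant from the delay
#' span, amplitudes by linear least squares at those constants). For the
#' `biphasic_rise` form the time constants are ordered `tau1 < tau2`
#' post hoc. If the two constants converge to within 10% of each other
#' the result carries an ill-conditioning flag.
#'
#' @inheritParams fit_monoexponential
#' @param form `"biphasic_rise"` or `"decay_plus_rise"`.
#' @param start Optional named list (`A1`, `tau1`, `A2`, `tau2`).
#' @return A `kinetic_fit` object.
#' @export
fit_biphasic <- function(trace, form = c("biphasic_rise", "decay_plus_rise"),
                         start = NULL, irf_fwhm = 0) {
  form <- match.arg(form)
  check_trace(trace)
  t <- trace$delay_ps
  if (is.null(start)) {
    start <- start_biphasic(t, trace$dA_mOD, form, tau1 = 1,
                            tau2 = max(t) / 4)
  }
  fit <- run_nls(trace, form, start,
                 lower = c(A1 = -Inf, tau1 = 1e-4, A2 = -Inf, tau2 = 1e-4),
                 irf_fwhm)
  finalize_fit(fit, form, start, trace, irf_fwhm)
}

finalize_fit <- function(fit, form, start, trace, irf_fwhm) {
  if (inherits(fit, "error")) {
    y0 <- kinetic_curve(form, trace$delay_ps, start, irf_fwhm)
    cf <- unlist(start)
    return(new_kinetic_fit(form, cf, rep(NA_real_, length(cf)),
                           sqrt(mean((trace$dA_mOD - y0)^2)),
                           converged = FALSE, trace, y0))
  }
  cf <- stats::coef(fit)
  ses <- tryCatch(
    summary(fit)$coefficients[, "Std. Error"],
    error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                        names(cf)))
  fitted_y <- kinetic_curve(form, trace$delay_ps, as.list(cf), irf_fwhm)
  ill <- FALSE
  if (form %in% c("biphasic_rise", "decay_plus_rise")) {
    t1 <- cf[["tau1"]]; t2 <- cf[["tau2"]]
    if (abs(t1 - t2) < 0.1 * max(t1, t2)) ill <- TRUE
    if (form == "biphasic_rise" && t1 > t2) {
      cf <- cf[c("A2", "tau2", "A1", "tau1")]
      ses <- ses[c("A2", "tau2", "A1", "tau1")]
      names(cf) <- names(ses) <- c("A1", "tau1", "A2", "tau2")
    }
  }
  new_kinetic_fit(form, cf, ses,
                  sqrt(mean(fit$fvec^2)),
                  converged = fit$info %in% 1:4, trace, fitted_y,
                  ill_conditioned = ill)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Global fit with shared time constants across traces
#'
#' Simultaneous least squares over several transients: the selected time
#' constants are shared by all traces while every trace keeps its own
#' amplitudes (and its own copy of any unshared constant). Residuals from
#' all traces are stacked, so unequal delay grids are allowed.
#'
#' @param traces List of transient tibbles (`delay_ps`, `dA_mOD`).
#' @param form `"biphasic_rise"` or `"decay_plus_rise"`.
#' @param shared Character vector among `c("tau1", "tau2")`; default shares
#'   only the slow constant.
#' @param start Optional list with entries `tau1`, `tau2` (scalars for
#'   shared, vectors per trace for unshared).
#' @param irf_fwhm Gaussian IRF FWHM, ps.
#' @return A `kinetic_fit`; shared constants appear in `$parameters`,
#'   per-trace amplitudes (and unshared constants) in `$amplitudes`.
#' @export
global_fit <- function(traces, form = c("biphasic_rise", "decay_plus_rise"),
                       shared = "tau2", start = NULL, irf_fwhm = 0) {
  form <- match.arg(form)
  if (!is.list(traces) || length(traces) < 2) {
    stop("global_fit needs a list of at least two traces", call. = FALSE)
  }
  lapply(traces, check_trace)
  stopifnot(all(shared %in% c("tau1", "tau2")), length(shared) >= 1)
  nt <- length(traces)

  singles <- lapply(traces, function(tr)
    fit_biphasic(tr, form, irf_fwhm = irf_fwhm))
  get_par <- function(f, nm) f$parameters$estimate[f$parameters$term == nm]
  tau1s <- vapply(singles, get_par, numeric(1), "tau1")
  tau2s <- vapply(singles, get_par, numeric(1), "tau2")
  if (is.null(start)) {
    start <- list(tau1 = if ("tau1" %in% shared) stats::median(tau1s) else
      tau1s, tau2 = if ("tau2" %in% shared) stats::median(tau2s) else tau2s)
  }

  # parameter vector: shared taus, then per-trace (unshared taus, A1, A2)
  pack <- function(tau1, tau2, amps) {
    p <- c()
    if ("tau1" %in% shared) p <- c(p, ltau1 = log(tau1[1]))
    if ("tau2" %in% shared) p <- c(p, ltau2 = log(tau2[1]))
    for (i in seq_len(nt)) {
      if (!("tau1" %in% shared)) p <- c(p, stats::setNames(log(tau1[i]),
                                                 paste0("ltau1_", i)))
      if (!("tau2" %in% shared)) p <- c(p, stats::setNames(log(tau2[i]),
                                                 paste0("ltau2_", i)))
      p <- c(p, stats::setNames(amps[[i]], paste0(c("A1_", "A2_"), i)))
    }
    p
  }
  unpack <- function(p) {
    lapply(seq_len(nt), function(i) {
      list(
        A1 = p[[paste0("A1_", i)]],
        tau1 = exp(if ("tau1" %in% shared) p[["ltau1"]] else
          p[[paste0("ltau1_", i)]]),
        A2 = p[[paste0("A2_", i)]],
        tau2 = exp(if ("tau2" %in% shared) p[["ltau2"]] else
          p[[paste0("ltau2_", i)]])
      )
    })
  }
  amps0 <- lapply(seq_len(nt), function(i)
    c(get_par(singles[[i]], "A1"), get_par(singles[[i]], "A2")))
  p0 <- pack(rep(start$tau1, length.out = nt), rep(start$tau2,
                                                   length.out = nt), amps0)
  residual <- function(p) {
    pl <- as.list(p)
    prs <- unpack(pl)
    unlist(lapply(seq_len(nt), function(i) {
      traces[[i]]$dA_mOD -
        kinetic_curve(form, traces[[i]]$delay_ps, prs[[i]], irf_fwhm)
    }))
  }
  res <- minpack.lm::nls.lm(par = as.list(p0), fn = residual,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300))
  sm <- summary(res)
  est <- stats::coef(res)
  ses <- sm$coefficients[, "Std. Error"]
  prs <- unpack(as.list(est))

  # delta method for log-parameterised taus: se(tau) = tau * se(log tau)
  coefs <- c()
  sevec <- c()
  if ("tau1" %in% shared) {
    coefs <- c(coefs, tau1 = exp(est[["ltau1"]]))
    sevec <- c(sevec, tau1 = exp(est[["ltau1"]]) * ses[["ltau1"]])
  }
  if ("tau2" %in% shared) {
    coefs <- c(coefs, tau2 = exp(est[["ltau2"]]))
    sevec <- c(sevec, tau2 = exp(est[["ltau2"]]) * ses[["ltau2"]])
  }
  amplitudes <- dplyr::bind_rows(lapply(seq_len(nt), function(i) {
    tibble::tibble(trace = i, A1 = prs[[i]]$A1, tau1 = prs[[i]]$tau1,
                   A2 = prs[[i]]$A2, tau2 = prs[[i]]$tau2)
  }))
  rss <- sum(residual(as.list(est))^2)
  ntot <- sum(vapply(traces, nrow, 0L))
  new_kinetic_fit(form, coefs, sevec, sqrt(rss / ntot),
                  converged = res$info %in% 1:4, traces,
                  fitted = NULL, amplitudes = amplitudes)
}
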
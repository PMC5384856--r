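get_est <- function(fit, term) {
  fit$parameters$estimate[fit$parameters$term == term]
}

test_that("simulation is deterministic and unbiased", {
  d <- log_delays(0.2, 100, 40)
  p <- list(A1 = 0.9, tau1 = 1.1, A2 = 0.3, tau2 = 11)
  clean <- simulate_transient("biphasic_rise", d, p, noise_sigma = 0)
  expect_equal(clean$dA_mOD, kinetic_curve("biphasic_rise", d, p))
  t1 <- simulate_transient("biphasic_rise", d, p, seed = 7)
  t2 <- simulate_transient("biphasic_rise", d, p, seed = 7)
  expect_identical(t1$dA_mOD, t2$dA_mOD)
  # replicate mean converges to the model curve
  reps <- vapply(1:1000, function(i)
    simulate_transient("biphasic_rise", d, p, seed = i)$dA_mOD,
    numeric(length(d)))
  se <- 0.03 / sqrt(1000)
  expect_lt(max(abs(rowMeans(reps) - clean$dA_mOD)), 4 * se)
  expect_error(simulate_transient("biphasic_rise", rev(d), p, seed = 1),
               "strictly increasing")
})

test_that("noiseless parameter recovery from perturbed starts, all forms", {
  d <- log_delays(0.2, 60, 60)
  cases <- list(
    list(form = "mono_decay_offset", p = list(A = -2, tau = 1.5, C = -0.1)),
    list(form = "biphasic_rise", p = list(A1 = 1.5, tau1 = 1.1, A2 = 0.5,
                                          tau2 = 11)),
    list(form = "decay_plus_rise", p = list(A1 = 1.0, tau1 = 1.1, A2 = 0.4,
                                            tau2 = 17))
  )
  for (cs in cases) {
    tr <- simulate_transient(cs$form, d, cs$p, noise_sigma = 0)
    start <- lapply(cs$p, function(v) if (v != 0) v * 1.5 else 0.1)
    fit <- if (cs$form == "mono_decay_offset") {
      fit_monoexponential(tr, start = start)
    } else {
      fit_biphasic(tr, cs$form, start = start)
    }
    expect_true(fit$converged)
    for (nm in names(cs$p)) {
      expect_equal(get_est(fit, nm), cs$p[[nm]], tolerance = 1e-6,
                   label = paste(cs$form, nm))
    }
    # and from -50% perturbed starts
    start2 <- lapply(cs$p, function(v) if (v != 0) v * 0.5 else -0.1)
    fit2 <- if (cs$form == "mono_decay_offset") {
      fit_monoexponential(tr, start = start2)
    } else {
      fit_biphasic(tr, cs$form, start = start2)
    }
    expect_equal(get_est(fit2, names(cs$p)[2]), cs$p[[2]], tolerance = 1e-6)
  }
})

test_that("automatic starts recover a noiseless mono-exponential exactly", {
  d <- seq(0.2, 8, length.out = 60)
  tr <- simulate_transient("mono_decay_offset", d,
                           list(A = -2, tau = 1.5, C = -0.1),
                           noise_sigma = 0)
  fit <- fit_monoexponential(tr)
  expect_equal(get_est(fit, "tau"), 1.5, tolerance = 1e-6)
})

test_that("covariance-based uncertainties match Monte-Carlo spread", {
  d <- seq(0.2, 8, length.out = 60)
  p <- list(A = -2, tau = 1.0, C = -0.1)
  taus <- ses <- numeric(150)
  for (i in seq_len(150)) {
    tr <- simulate_transient("mono_decay_offset", d, p, noise_sigma = 0.03,
                             seed = 4000 + i)
    fit <- fit_monoexponential(tr)
    taus[i] <- get_est(fit, "tau")
    ses[i] <- fit$parameters$std_error[fit$parameters$term == "tau"]
  }
  expect_lt(abs(mean(ses) - sd(taus)) / sd(taus), 0.30)
})

test_that("decay_plus_rise nests the mono-exponential", {
  d <- seq(0.2, 20, length.out = 80)
  # noiseless: the wider model collapses onto the mono-exponential exactly
  tr0 <- simulate_transient("mono_decay_offset", d,
                            list(A = 1.5, tau = 1.2, C = 0),
                            noise_sigma = 0)
  expect_equal(get_est(fit_biphasic(tr0, "decay_plus_rise"), "tau1"), 1.2,
               tolerance = 1e-4)
  # with noise the spurious slow component can absorb a little signal;
  # the fast constant still agrees within the fit uncertainties (the
  # wider model's covariance can be singular when A2 ~ 0, so fall back on
  # the mono fit's scale)
  tr <- simulate_transient("mono_decay_offset", d,
                           list(A = 1.5, tau = 1.2, C = 0),
                           noise_sigma = 0.03, seed = 11)
  fm <- fit_monoexponential(tr)
  fb <- fit_biphasic(tr, "decay_plus_rise")
  tau_m <- get_est(fm, "tau")
  se_m <- fm$parameters$std_error[fm$parameters$term == "tau"]
  expect_lt(abs(get_est(fb, "tau1") - tau_m), max(5 * se_m, 0.15))
})

test_that("a pure water-like decay does not hallucinate a slow rise", {
  d <- log_delays(0.2, 100, 80)
  hallucinated <- 0L
  for (i in 1:20) {
    tr <- simulate_transient("decay_plus_rise", d,
                             list(A1 = 1.0, tau1 = 1.1, A2 = 0, tau2 = 15),
                             noise_sigma = 0.03, seed = 600 + i)
    fb <- fit_biphasic(tr, "decay_plus_rise")
    a2 <- get_est(fb, "A2")
    se2 <- fb$parameters$std_error[fb$parameters$term == "A2"]
    if (is.finite(se2) && abs(a2) > 3 * se2) hallucinated <- hallucinated + 1L
  }
  expect_lte(hallucinated, 2L)
})

test_that("fit is gauge-invariant under joint rescaling of the data", {
  d <- log_delays(0.2, 100, 60)
  tr <- simulate_transient("biphasic_rise", d,
                           list(A1 = 0.9, tau1 = 1.1, A2 = 0.3, tau2 = 11),
                           noise_sigma = 0.03, seed = 5)
  f1 <- fit_biphasic(tr, "biphasic_rise")
  tr10 <- tr
  tr10$dA_mOD <- tr$dA_mOD * 10
  f10 <- fit_biphasic(tr10, "biphasic_rise")
  expect_equal(get_est(f10, "tau1"), get_est(f1, "tau1"), tolerance = 1e-5)
  expect_equal(get_est(f10, "tau2"), get_est(f1, "tau2"), tolerance = 1e-5)
  expect_equal(get_est(f10, "A1"), 10 * get_est(f1, "A1"), tolerance = 1e-5)
})

test_that("biphasic time constants are ordered and flagged when degenerate", {
  d <- log_delays(0.2, 100, 60)
  tr <- simulate_transient("biphasic_rise", d,
                           list(A1 = 0.9, tau1 = 1.1, A2 = 0.3, tau2 = 11),
                           noise_sigma = 0, seed = NULL)
  # start with swapped roles: ordering is restored post hoc
  fit <- fit_biphasic(tr, "biphasic_rise",
                      start = list(A1 = 0.3, tau1 = 12, A2 = 0.9, tau2 = 1))
  expect_lt(get_est(fit, "tau1"), get_est(fit, "tau2"))
  expect_equal(get_est(fit, "tau1"), 1.1, tolerance = 1e-4)
  # near-degenerate constants raise the ill-conditioning flag (noiseless
  # data and near-truth starts so the fit actually lands on the
  # degenerate pair)
  tr2 <- simulate_transient("biphasic_rise", d,
                            list(A1 = 0.5, tau1 = 5, A2 = 0.5, tau2 = 5.2),
                            noise_sigma = 0)
  f2 <- fit_biphasic(tr2, "biphasic_rise",
                     start = list(A1 = 0.5, tau1 = 4.8, A2 = 0.5,
                                  tau2 = 5.4))
  expect_true(f2$ill_conditioned)
})

test_that("IRF convolution reduces to the plain model away from zero and
           broadens near zero", {
  d <- seq(0.2, 10, length.out = 50)
  p <- list(A = -2, tau = 1.5, C = -0.1)
  plain <- kinetic_curve("mono_decay_offset", d, p, irf_fwhm = 0)
  conv <- kinetic_curve("mono_decay_offset", d, p, irf_fwhm = 0.1)
  expect_equal(conv[d > 1], plain[d > 1], tolerance = 1e-3)
  t0 <- seq(-0.5, 0.5, by = 0.01)
  c0 <- kinetic_curve("mono_decay_offset", t0, p, irf_fwhm = 0.2)
  expect_true(all(is.finite(c0)))
  expect_lt(abs(c0[t0 == -0.5]), 1e-3)
})

test_that("global fit shares constants and pools information", {
  d <- log_delays(0.2, 100, 60)
  p <- list(A1 = 1.5, tau1 = 1.0, A2 = 0.5, tau2 = 17)
  clean <- simulate_transient("biphasic_rise", d, p, noise_sigma = 0)
  gf0 <- global_fit(list(clean, clean), "biphasic_rise", shared = "tau2")
  single <- fit_biphasic(clean, "biphasic_rise")
  expect_equal(get_est(gf0, "tau2"), get_est(single, "tau2"),
               tolerance = 1e-5)
  expect_error(global_fit(list(clean), "biphasic_rise"), "at least two")

  # pooling: shared-constant estimates scatter less than per-trace ones
  shared_tau <- per_tau <- matrix(NA_real_, 12, 1)
  per_all <- numeric(0)
  for (r in 1:12) {
    traces <- lapply(1:4, function(i)
      simulate_transient("biphasic_rise", d,
                         list(A1 = 1.5, tau1 = 0.9 + 0.1 * i, A2 = 0.5,
                              tau2 = 17),
                         noise_sigma = 0.03, seed = 7000 + 10 * r + i))
    gf <- global_fit(traces, "biphasic_rise", shared = "tau2")
    shared_tau[r] <- get_est(gf, "tau2")
    per_all <- c(per_all, vapply(traces, function(tr)
      get_est(fit_biphasic(tr, "biphasic_rise"), "tau2"), numeric(1)))
  }
  expect_lt(var(shared_tau[, 1]), var(per_all))
  expect_equal(mean(shared_tau), 17, tolerance = 0.15)
})

test_that("tidy and glance expose the fit in broom form", {
  d <- seq(0.2, 8, length.out = 40)
  tr <- simulate_transient("mono_decay_offset", d,
                           list(A = -2, tau = 1, C = -0.1),
                           noise_sigma = 0.03, seed = 2)
  fit <- fit_monoexponential(tr)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("A", "tau", "C"))
  expect_true(all(td$std_error >= 0))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_gt(gl$sigma, 0)
})
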
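harmonic <- function(k) function(x) 0.5 * k * sum(x^2)
kB <- 0.008314462618

test_that("harmonic-well sampling reproduces the Boltzmann variance kT/k", {
  k <- 1 # kJ/mol/A^2
  p <- mc_params(temperature = 298, seed = 1234, n_sweeps = 1e5,
                 equilibration_fraction = 0.05, max_translation = 2.5,
                 sample_stride = 1)
  s <- mc_sample_custom(harmonic(k), c(0, 0, 0), p)
  target <- kB * 298 / k
  v <- apply(s[, c("x1", "x2", "x3")], 2, var)
  for (vi in v) expect_lt(abs(vi - target) / target, 0.05)
  # sampled marginal matches the Gaussian closed form (KS distance)
  thin <- s$x1[seq(1, nrow(s), by = 10)]
  D <- suppressWarnings(ks.test(thin, "pnorm", 0, sqrt(target)))$statistic
  expect_lt(unname(D), 0.03)
  acc <- attr(s, "acceptance")
  expect_gt(acc, 0.05)
  expect_lt(acc, 0.95)
})

test_that("zero-temperature limit accepts only downhill moves", {
  p <- mc_params(temperature = 1e-9, seed = 5, n_sweeps = 2000,
                 equilibration_fraction = 0, max_translation = 0.5,
                 sample_stride = 1)
  s <- mc_sample_custom(harmonic(2), c(4, -3, 2), p)
  expect_true(all(diff(s$energy) <= 1e-12))
})

test_that("identical seeds give bit-identical trajectories", {
  sol <- dmp_solute()
  cell <- simulation_cell("droplet", 7)
  p <- mc_params(temperature = 298, seed = 99, n_sweeps = 200,
                 equilibration_fraction = 0.2, sample_stride = 20)
  t1 <- suppressMessages(mc_sample(sol, 20, cell, p))
  t2 <- suppressMessages(mc_sample(sol, 20, cell, p))
  expect_identical(t1$x, t2$x)
  expect_identical(t1$z, t2$z)
  p2 <- mc_params(temperature = 298, seed = 100, n_sweeps = 200,
                  equilibration_fraction = 0.2, sample_stride = 20)
  t3 <- suppressMessages(mc_sample(sol, 20, cell, p2))
  expect_false(identical(t1$x, t3$x))
})

test_that("droplet sampling: wall respected, acceptance sane, energy matches
           the independent R implementation", {
  sol <- dmp_solute()
  cell <- simulation_cell("droplet", 7)
  p <- mc_params(temperature = 298, seed = 21, n_sweeps = 600,
                 equilibration_fraction = 0.25, sample_stride = 50)
  traj <- suppressMessages(mc_sample(sol, 25, cell, p))
  st <- attr(traj, "stats")
  expect_gt(st$acceptance, 0.05)
  expect_lt(st$acceptance, 0.95)
  ox <- dplyr::filter(tibble::as_tibble(traj), species == "water",
                      site == "O")
  expect_true(all(ox$x^2 + ox$y^2 + ox$z^2 <= cell$size^2 + 1e-9))
  for (fi in unique(traj$frame)) {
    fd <- dplyr::filter(tibble::as_tibble(traj), frame == fi)
    expect_equal(potential_energy(fd, cell, solute = sol),
                 st$energy$energy[st$energy$frame == fi], tolerance = 1e-9)
  }
})

test_that("recorded energies are stationary after equilibration", {
  sol <- dmp_solute()
  cell <- simulation_cell("droplet", 7)
  p <- mc_params(temperature = 310, seed = 31, n_sweeps = 4000,
                 equilibration_fraction = 0.5, sample_stride = 20)
  traj <- suppressMessages(mc_sample(sol, 25, cell, p))
  en <- attr(traj, "stats")$energy$energy
  # slope test on block means: no significant monotone drift
  nb <- 10
  bm <- vapply(split(en, cut(seq_along(en), nb, labels = FALSE)), mean,
               numeric(1))
  fit <- summary(lm(bm ~ seq_len(nb)))
  expect_gt(fit$coefficients[2, "Pr(>|t|)"], 0.01)
})

test_that("impossible initial packing raises an initialization error", {
  sol <- dmp_solute()
  cell <- simulation_cell("droplet", 4)
  p <- mc_params(temperature = 298, seed = 1, n_sweeps = 10)
  expect_error(suppressMessages(mc_sample(sol, 500, cell, p)),
               "initialization error")
})
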
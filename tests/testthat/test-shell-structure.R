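# trajectory of bare points (no solute): place single-site "waters" is not
# possible, so ideal-gas tests build the site-record tibble directly
ideal_gas_traj <- function(n_frames, n_per_frame, radius, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_frames), function(fi) {
    # uniform in the ball by rejection
    pts <- matrix(NA_real_, n_per_frame, 3)
    got <- 0
    while (got < n_per_frame) {
      cand <- matrix(runif(3 * n_per_frame, -radius, radius), ncol = 3)
      ok <- rowSums(cand^2) <= radius^2
      take <- min(n_per_frame - got, sum(ok))
      if (take > 0) {
        pts[(got + 1):(got + take), ] <- cand[ok, , drop = FALSE][seq_len(take), ]
        got <- got + take
      }
    }
    tibble::tibble(frame = fi, species = "water",
                   molecule = seq_len(n_per_frame), site = "O",
                   x = pts[, 1], y = pts[, 2], z = pts[, 3], charge = 0)
  })
  ref <- tibble::tibble(frame = seq_len(n_frames), species = "solute",
                        molecule = 0L, site = "REF", x = 0, y = 0, z = 0,
                        charge = 0)
  shellfield:::new_trajectory(
    dplyr::bind_rows(dplyr::bind_rows(rows), ref), 298,
    simulation_cell("droplet", radius), NULL, water_model())
}

test_that("ideal-gas RDF is flat within 3-sigma Poisson bands", {
  R <- 10
  traj <- ideal_gas_traj(n_frames = 100, n_per_frame = 1000, radius = R,
                         seed = 42)
  rd <- radial_distribution(traj, site_selection("solute", "REF"),
                            site_selection("water", "O"), r_max = 8,
                            n_bins = 40)
  # expected counts per bin for g = 1
  rho <- attr(rd, "density")
  edges <- attr(rd, "edges")
  shell <- 4 / 3 * pi * diff(edges^3)
  expected <- 100 * rho * shell
  use <- rd$r > 1
  dev <- abs(rd$count[use] - expected[use]) / sqrt(expected[use])
  expect_lt(max(dev), 3.5)
  expect_true(all(rd$g >= 0))
  # outer half averages to 1
  expect_lt(abs(mean(rd$g[rd$r > 4]) - 1), 0.1)
})

test_that("single-pair RDF puts all mass in the distance bin", {
  d <- 3.3
  df <- tibble::tibble(
    frame = 1L, species = c("solute", "water"), molecule = c(0L, 1L),
    site = c("REF", "O"), x = c(0, d), y = 0, z = 0, charge = 0)
  traj <- shellfield:::new_trajectory(df, 298, simulation_cell("droplet", 8),
                                      NULL, water_model())
  rd <- radial_distribution(traj, site_selection("solute", "REF"),
                            site_selection("water", "O"), r_max = 8,
                            n_bins = 16)
  expect_equal(sum(rd$count), 1)
  expect_equal(rd$count[findInterval(d, attr(rd, "edges"))], 1)
})

test_that("bin refinement conserves integrated counts", {
  traj <- ideal_gas_traj(10, 200, 8, seed = 9)
  rd1 <- radial_distribution(traj, site_selection("solute", "REF"),
                             site_selection("water", "O"), r_max = 6,
                             n_bins = 20)
  rd2 <- radial_distribution(traj, site_selection("solute", "REF"),
                             site_selection("water", "O"), r_max = 6,
                             n_bins = 40)
  expect_equal(sum(rd1$count), sum(rd2$count))
  # pairwise: each coarse bin equals the sum of its two fine bins
  expect_equal(rd1$count, rd2$count[c(TRUE, FALSE)] + rd2$count[c(FALSE, TRUE)])
  expect_error(radial_distribution(traj, site_selection("solute", "XX"),
                                   site_selection("water", "O"), 6, 20),
               "selection error")
  expect_error(radial_distribution(traj, site_selection("solute", "REF"),
                                   site_selection("water", "O"), r_max = 20,
                                   n_bins = 20),
               "geometry error")
})

fake_samples <- function(v, temperature = 298) {
  tibble::tibble(frame = seq_along(v), temperature = temperature,
                 E_parallel = v)
}

test_that("field distribution: normalisation, mean consistency, errors", {
  d <- field_distribution(fake_samples(rep(-42.5, 10)), binwidth = 2)
  expect_equal(sum(d$occurrence), 1, tolerance = 1e-12)
  expect_equal(sum(d$occurrence > 0), 1)
  expect_equal(attr(d, "mean"), -42.5)
  set.seed(8)
  v <- rnorm(4000, mean = -80, sd = 7)
  d2 <- field_distribution(fake_samples(v), binwidth = 2)
  expect_equal(sum(d2$occurrence), 1, tolerance = 1e-12)
  # histogram mean equals bin-free mean (carried in the attribute)
  expect_equal(attr(d2, "mean"), mean(v), tolerance = 1e-12)
  # and within 3 SE of the generator mean
  expect_lt(abs(attr(d2, "mean") + 80), 3 * 7 / sqrt(4000))
  mixed <- dplyr::bind_rows(fake_samples(v, 298), fake_samples(v, 330))
  expect_error(field_distribution(mixed), "mixed temperatures")
})

test_that("occurrence differences sum to zero and locate shifted extrema", {
  set.seed(13)
  edges <- seq(-40, 40, by = 1)
  sd0 <- 8
  delta <- 0.8  # small against sigma
  v1 <- rnorm(2e5, delta / 2, sd0)
  v2 <- rnorm(2e5, -delta / 2, sd0)
  d1 <- field_distribution(fake_samples(v1, 330), edges = edges)
  d2 <- field_distribution(fake_samples(v2, 298), edges = edges)
  od <- occurrence_difference(d1, d2)
  expect_lt(abs(sum(od$difference)), 1e-9)
  # identical inputs give the zero difference
  od0 <- occurrence_difference(d1, d1)
  expect_true(all(od0$difference == 0))
  # dense-grid analytic oracle: difference of shifted normal densities;
  # for delta << sigma the extrema sit near +-sigma, separation ~ 2 sigma
  xs <- seq(-40, 40, by = 0.001)
  dens <- dnorm(xs, delta / 2, sd0) - dnorm(xs, -delta / 2, sd0)
  oracle_sep <- abs(xs[which.max(dens)] - xs[which.min(dens)])
  expect_equal(attr(od, "separation"), oracle_sep, tolerance = 0.15)
  expect_equal(oracle_sep, 2 * sd0, tolerance = 0.01)
  # mismatched grids are refused
  d3 <- field_distribution(fake_samples(v1, 330),
                           edges = seq(-42, 42, by = 1))
  expect_error(occurrence_difference(d3, d2), "grid error")
})

test_that("mean-field change recovers a constructed -5 MV/cm shift", {
  set.seed(77)
  hot <- field_distribution(fake_samples(rnorm(3000, -80, 6), 330),
                            binwidth = 2)
  cold <- field_distribution(fake_samples(rnorm(3000, -85, 6), 298),
                             binwidth = 2)
  # amplitudes: hot mean 80, cold 85 in magnitude; signed change of the
  # magnitude-like construction used here: -80 - (-85) = +5, i.e. a 5 MV/cm
  # reduction of the field amplitude on heating
  mfc <- mean_field_change(hot, cold, seed = 3)
  expect_lt(abs(mfc$delta_mean - 5), 3 * mfc$se)
  # antisymmetry under argument swap
  mfc2 <- mean_field_change(cold, hot, seed = 3)
  expect_equal(mfc$delta_mean, -mfc2$delta_mean)
  # identical inputs give zero
  expect_equal(mean_field_change(hot, hot, seed = 1)$delta_mean, 0)
})

test_that("block error gives a sane autocorrelation-aware estimate", {
  set.seed(5)
  be <- block_error(fake_samples(rnorm(1000, -80, 5)), n_blocks = 10)
  expect_equal(be$mean, -80, tolerance = 1)
  expect_gt(be$se_block, 0)
})
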
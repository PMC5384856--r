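#' Monte-Carlo run parameters
#'
#' Parameters of a rigid-body Metropolis run. A seed is mandatory: there is
#' no hidden global random state, identical parameters give bit-identical
#' trajectories. The defaults are the desk-scale production settings
#' (2e5 sweeps, first 20% discarded, one frame every 100 sweeps).
#'
#' @param temperature Kelvin, > 0.
#' @param seed Integer RNG seed (required).
#' @param n_sweeps Number of MC sweeps (one sweep = one attempted move per
#'   molecule).
#' @param equilibration_fraction Fraction of sweeps discarded before
#'   recording, in \[0, 1).
#' @param max_translation Maximum displacement per move, Angstrom.
#' @param max_rotation Maximum rotation per move, radians.
#' @param sample_stride Record one frame every this many sweeps.
#' @return An object of class `mc_params`.
#' @export
mc_params <- function(temperature, seed, n_sweeps = 2e5,
                      equilibration_fraction = 0.2, max_translation = 0.25,
                      max_rotation = 0.35, sample_stride = 100) {
  stopifnot(is.numeric(temperature), temperature > 0,
            n_sweeps >= 1, equilibration_fraction >= 0,
            equilibration_fraction < 1, max_translation > 0,
            max_rotation > 0, sample_stride >= 1)
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("an explicit integer `seed` is required", call. = FALSE)
  }
  structure(list(temperature = temperature, n_sweeps = as.integer(n_sweeps),
                 equilibration_fraction = equilibration_fraction,
                 max_translation = max_translation,
                 max_rotation = max_rotation, seed = as.integer(seed),
                 sample_stride = as.integer(sample_stride)),
            class = "mc_params")
}

# random non-overlapping initial placement; deterministic given the seed
init_waters <- function(solute, n_waters, cell, min_ow = 2.5, min_os = 2.3,
                        max_tries = 20000) {
  inside <- function(p) {
    if (cell$kind == "droplet") sum(p^2) <= (cell$size - 0.6)^2 else TRUE
  }
  draw <- function() {
    if (cell$kind == "droplet") {
      repeat {
        p <- stats::runif(3, -cell$size, cell$size)
        if (sum(p^2) <= (cell$size - 0.6)^2) return(p)
      }
    } else {
      stats::runif(3, -cell$size / 2, cell$size / 2)
    }
  }
  spos <- if (is.null(solute)) matrix(0, 0, 3) else
    as.matrix(solute$atoms[, c("x", "y", "z")])
  placed <- matrix(NA_real_, n_waters, 3)
  for (i in seq_len(n_waters)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- draw()
      if (nrow(spos) > 0 &&
          min(sqrt(colSums((t(spos) - p)^2))) < min_os) next
      if (i > 1) {
        prev <- placed[seq_len(i - 1), , drop = FALSE]
        d <- sqrt((prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2 +
                    (prev[, 3] - p[3])^2)
        if (cell$kind == "cubic") {
          # conservative: also check nearest images along axes
          d <- pmin(d, abs(cell$size - d))
        }
        if (min(d) < min_ow) next
      }
      placed[i, ] <- p
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("initialization error: could not place waters without overlap; ",
           "reduce n_waters or enlarge the cell", call. = FALSE)
    }
  }
  placed
}

#' Sample hydration-shell configurations by Metropolis Monte Carlo
#'
#' Generates an equilibrium ensemble of rigid five-site waters around a
#' rigid solute at the requested temperature. Moves are single-molecule
#' rigid translations plus rotations, accepted with probability
#' min(1, exp(-dU/kT)). The solute never moves. In a droplet cell a hard
#' spherical wall confines the water oxygens; in a cubic cell the
#' minimum-image convention applies with a molecule-based cutoff.
#'
#' The mean acceptance fraction is reported via [message()] and stored in
#' the trajectory's `stats` attribute together with per-frame energies.
#'
#' @param solute A [dmp_solute()] geometry, or `NULL` for neat water.
#' @param n_waters Number of water molecules (>= 1).
#' @param cell A [simulation_cell()].
#' @param params An [mc_params()] object.
#' @param model Water model; defaults to TIP5P.
#' @param cutoff Pair cutoff in Angstrom (periodic cells only).
#' @return A `shell_trajectory` tibble (see [frame_from_waters()] for the
#'   column layout) with attributes `temperature`, `cell`, `solute`,
#'   `water_model` and `stats`.
#' @export
mc_sample <- function(solute, n_waters, cell, params, model = water_model(),
                      cutoff = 9) {
  stopifnot(inherits(params, "mc_params"), inherits(cell, "simulation_cell"),
            n_waters >= 1)
  set.seed(params$seed)
  opos <- init_waters(solute, n_waters, cell)
  quats <- t(vapply(seq_len(n_waters), function(i) quat_random_uniform(),
                    numeric(4)))
  body <- as.matrix(model$sites[, c("x", "y", "z")])
  has_sol <- !is.null(solute)
  spos <- if (has_sol) as.matrix(solute$atoms[, c("x", "y", "z")]) else
    matrix(0, 0, 3)
  equil <- as.integer(floor(params$n_sweeps * params$equilibration_fraction))

  res <- .mc_run_cpp(
    opos, quats, body, model$sites$charge,
    model$lennard_jones$sigma, model$lennard_jones$epsilon,
    spos,
    if (has_sol) solute$atoms$charge else numeric(0),
    if (has_sol) solute$atoms$sigma else numeric(0),
    if (has_sol) solute$atoms$epsilon else numeric(0),
    cell$kind == "cubic", cell$size, cutoff,
    params$temperature, params$n_sweeps, equil,
    params$max_translation, params$max_rotation, params$sample_stride,
    .coulomb_kJ_mol(), .KB_KJ_MOL
  )

  nf <- res$n_frames
  nsite <- nrow(model$sites)
  arr <- array(res$sites, dim = c(3, nsite, n_waters, nf))
  wtb <- tibble::tibble(
    frame = rep(seq_len(nf), each = nsite * n_waters),
    species = "water",
    molecule = rep(rep(seq_len(n_waters), each = nsite), nf),
    site = rep(model$sites$site, n_waters * nf),
    x = as.vector(arr[1, , , ]),
    y = as.vector(arr[2, , , ]),
    z = as.vector(arr[3, , , ]),
    charge = rep(model$sites$charge, n_waters * nf)
  )
  if (has_sol) {
    stb <- tibble::tibble(
      frame = rep(seq_len(nf), each = nrow(solute$atoms)),
      species = "solute", molecule = 0L,
      site = rep(solute$atoms$label, nf),
      x = rep(solute$atoms$x, nf), y = rep(solute$atoms$y, nf),
      z = rep(solute$atoms$z, nf), charge = rep(solute$atoms$charge, nf)
    )
    wtb <- dplyr::arrange(dplyr::bind_rows(stb, wtb), .data$frame,
                          .data$molecule)
  }
  stats <- list(acceptance = res$acceptance, n_sweeps = params$n_sweeps,
                seed = params$seed,
                energy = tibble::tibble(frame = seq_len(nf),
                                        energy = res$energy))
  message(sprintf("mc_sample: %d frames, acceptance fraction %.3f",
                  nf, res$acceptance))
  new_trajectory(wtb, params$temperature, cell, solute, model, stats)
}

#' Metropolis sampling of an arbitrary potential (validation hook)
#'
#' Single-particle Metropolis sampler over a user-supplied potential energy
#' function, used to validate the acceptance rule against closed-form
#' Boltzmann statistics (e.g. an isotropic harmonic well, for which the
#' position variance per axis is kT/k).
#'
#' @param energy_fn Function mapping a coordinate vector to energy (kJ/mol).
#' @param x0 Numeric start coordinates.
#' @param params An [mc_params()] object (`max_rotation` is ignored).
#' @return Tibble with one row per recorded sample: `step`, coordinate
#'   columns `x1..xd`, `energy`; attribute `acceptance`.
#' @export
mc_sample_custom <- function(energy_fn, x0, params) {
  stopifnot(inherits(params, "mc_params"))
  set.seed(params$seed)
  kT <- .KB_KJ_MOL * params$temperature
  d <- length(x0)
  x <- as.numeric(x0)
  u <- energy_fn(x)
  equil <- floor(params$n_sweeps * params$equilibration_fraction)
  keep <- seq_len(params$n_sweeps) > equil &
    (seq_len(params$n_sweeps) - equil - 1) %% params$sample_stride == 0
  out <- matrix(NA_real_, sum(keep), d)
  es <- numeric(sum(keep))
  steps <- which(keep)
  acc <- 0L
  rec <- 0L
  for (s in seq_len(params$n_sweeps)) {
    xn <- x + stats::runif(d, -1, 1) * params$max_translation
    un <- energy_fn(xn)
    if (un - u <= 0 || stats::runif(1) < exp(-(un - u) / kT)) {
      x <- xn; u <- un; acc <- acc + 1L
    }
    if (keep[s]) {
      rec <- rec + 1L
      out[rec, ] <- x
      es[rec] <- u
    }
  }
  tb <- tibble::as_tibble(as.data.frame(out),
                          .name_repair = ~ paste0("x", seq_len(d)))
  tb <- dplyr::mutate(tb, step = steps, energy = es, .before = 1)
  attr(tb, "acceptance") <- acc / params$n_sweeps
  tb
}
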
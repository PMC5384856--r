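#' Point multipole source
#'
#' A field source carrying any combination of a point charge, a point
#' dipole and a Buckingham traceless quadrupole, for distributed-multipole
#' evaluation of the solvent field.
#'
#' @param position Numeric length-3, Angstrom.
#' @param charge Point charge, e.
#' @param dipole Numeric length-3 dipole, e Angstrom.
#' @param quadrupole 3x3 symmetric traceless matrix, e Angstrom^2.
#' @return An object of class `multipole_site`.
#' @export
multipole_site <- function(position, charge = 0, dipole = c(0, 0, 0),
                           quadrupole = matrix(0, 3, 3)) {
  stopifnot(length(position) == 3L, length(dipole) == 3L,
            is.matrix(quadrupole), all(dim(quadrupole) == c(3L, 3L)))
  if (max(abs(quadrupole - t(quadrupole))) > 1e-9) {
    stop("quadrupole must be symmetric", call. = FALSE)
  }
  if (abs(sum(diag(quadrupole))) > 1e-9) {
    stop("quadrupole must be traceless (Buckingham convention); see ",
         "quadrupole_from_moments()", call. = FALSE)
  }
  structure(list(position = as.numeric(position), charge = as.numeric(charge),
                 dipole = as.numeric(dipole), quadrupole = quadrupole),
            class = "multipole_site")
}

#' Traceless quadrupole from primitive second moments
#'
#' Converts a primitive second-moment matrix `M[i,j] = sum q x_i x_j`
#' (e Angstrom^2) to the Buckingham traceless form
#' `Theta = (3 M - tr(M) I) / 2`.
#'
#' @param moments 3x3 symmetric matrix of primitive second moments.
#' @return 3x3 traceless symmetric matrix.
#' @export
quadrupole_from_moments <- function(moments) {
  stopifnot(is.matrix(moments), all(dim(moments) == c(3L, 3L)))
  (3 * moments - sum(diag(moments)) * diag(3)) / 2
}

displacement <- function(site, point) {
  R <- as.numeric(point) - site$position
  r <- sqrt(sum(R^2))
  if (r < 1e-12) stop("field singularity: evaluation point coincides with ",
                      "the source site", call. = FALSE)
  list(R = R, r = r, n = R / r)
}

#' Coulomb field of a point charge
#'
#' `E = q R / |R|^3` (SI, reported in MV/cm), directed away from a positive
#' charge.
#'
#' @param site A [multipole_site()].
#' @param point Evaluation point, Angstrom.
#' @return Field 3-vector, MV/cm.
#' @export
field_from_charge <- function(site, point) {
  d <- displacement(site, point)
  field_constant() * site$charge * d$n / d$r^2
}

#' Field of an ideal point dipole
#'
#' `E = (3 (mu . n) n - mu) / r^3` in MV/cm for `mu` in e Angstrom.
#'
#' @inheritParams field_from_charge
#' @return Field 3-vector, MV/cm.
#' @export
field_from_dipole <- function(site, point) {
  d <- displacement(site, point)
  mu <- site$dipole
  field_constant() * (3 * sum(mu * d$n) * d$n - mu) / d$r^3
}

#' Field of a traceless point quadrupole
#'
#' Gradient field of the Buckingham quadrupole potential
#' `phi = (n . Theta n) / r^3` (the conventional 1/2 is absorbed in the
#' Buckingham definition `Theta = (3 M - tr(M) I)/2`):
#' `E = (5 (n . Theta n) n - 2 Theta n) / r^4` in MV/cm.
#'
#' @inheritParams field_from_charge
#' @return Field 3-vector, MV/cm.
#' @export
field_from_quadrupole <- function(site, point) {
  d <- displacement(site, point)
  Th <- site$quadrupole
  if (abs(sum(diag(Th))) > 1e-9) {
    stop("quadrupole must be traceless", call. = FALSE)
  }
  Tn <- as.numeric(Th %*% d$n)
  field_constant() * (5 * sum(d$n * Tn) * d$n - 2 * Tn) / d$r^4
}

#' Total field of one multipole site
#'
#' Sum of the charge, dipole and quadrupole contributions.
#' @inheritParams field_from_charge
#' @return Field 3-vector, MV/cm.
#' @export
field_from_site <- function(site, point) {
  field_from_charge(site, point) + field_from_dipole(site, point) +
    field_from_quadrupole(site, point)
}

# rotation matrix (body -> world) of each water in a frame, reconstructed
# from the O, H1, H2 site positions under the body-frame convention of the
# water model (H-O-H bisector along +z, hydrogens in the xz plane).
water_rotations <- function(frame_df) {
  w <- frame_df[frame_df$species == "water", ]
  mols <- unique(w$molecule)
  out <- lapply(mols, function(m) {
    s <- w[w$molecule == m, ]
    o <- unlist(s[s$site == "O", c("x", "y", "z")])
    h1 <- unlist(s[s$site == "H1", c("x", "y", "z")])
    h2 <- unlist(s[s$site == "H2", c("x", "y", "z")])
    ez <- (h1 + h2) / 2 - o
    ez <- ez / sqrt(sum(ez^2))
    ex <- h1 - h2
    ex <- ex - sum(ex * ez) * ez
    ex <- ex / sqrt(sum(ex^2))
    ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
            ez[3] * ex[1] - ez[1] * ex[3],
            ez[1] * ex[2] - ez[2] * ex[1])
    cbind(ex, ey, ez)
  })
  names(out) <- as.character(mols)
  out
}

#' Solvent electric field at the phosphate probe
#'
#' Superposition of the fields of all solvent (water) sites of one frame at
#' the probe point, projected on the C2 axis. The solute's own charges
#' never contribute. By default the water sites act as point charges
#' (consistent with the five-site sampling model); per-site dipoles and
#' quadrupoles given in the water body frame may be supplied for
#' distributed-multipole fidelity and are rotated with each molecule.
#'
#' @param frame Single-frame tibble in site-record form.
#' @param probe A [c2_probe()] object.
#' @param multipoles Optional tibble of body-frame per-site multipoles with
#'   columns `site`, `mux`, `muy`, `muz` and optionally `Qxx`, `Qxy`,
#'   `Qxz`, `Qyy`, `Qyz`, `Qzz` (traceless), e.g. from [read_multipoles()].
#' @return One-row tibble: `frame`, `Ex`, `Ey`, `Ez`, `E`, `E_parallel`
#'   (all MV/cm; `E_parallel = E . axis`, positive pointing from P through
#'   the O-O midpoint into the solvent).
#' @export
solvent_field <- function(frame, probe, multipoles = NULL) {
  stopifnot(inherits(probe, "field_probe"))
  w <- frame[frame$species == "water", ]
  fi <- if (nrow(frame)) frame$frame[1] else NA_integer_
  if (nrow(w) == 0) {
    warning("frame contains no waters; field is zero")
    return(tibble::tibble(frame = fi, Ex = 0, Ey = 0, Ez = 0, E = 0,
                          E_parallel = 0))
  }
  r0 <- probe$point
  dx <- r0[1] - w$x; dy <- r0[2] - w$y; dz <- r0[3] - w$z
  r2 <- dx^2 + dy^2 + dz^2
  if (any(r2 < 1e-12)) {
    stop(sprintf("field singularity in frame %d: water site coincides with ",
                 fi), "the probe point", call. = FALSE)
  }
  r3 <- r2^1.5
  k <- field_constant()
  E <- c(sum(k * w$charge * dx / r3),
         sum(k * w$charge * dy / r3),
         sum(k * w$charge * dz / r3))
  if (!is.null(multipoles)) {
    rots <- water_rotations(frame)
    has_q <- all(c("Qxx", "Qxy", "Qxz", "Qyy", "Qyz", "Qzz") %in%
                   names(multipoles))
    for (i in seq_len(nrow(w))) {
      mp <- multipoles[multipoles$site == w$site[i], ]
      if (nrow(mp) == 0) next
      R <- rots[[as.character(w$molecule[i])]]
      mu <- as.numeric(R %*% c(mp$mux, mp$muy, mp$muz))
      Th <- matrix(0, 3, 3)
      if (has_q) {
        Tb <- matrix(c(mp$Qxx, mp$Qxy, mp$Qxz,
                       mp$Qxy, mp$Qyy, mp$Qyz,
                       mp$Qxz, mp$Qyz, mp$Qzz), 3, 3)
        Th <- R %*% Tb %*% t(R)
      }
      ms <- multipole_site(c(w$x[i], w$y[i], w$z[i]), 0, mu, Th)
      E <- E + field_from_dipole(ms, r0) + field_from_quadrupole(ms, r0)
    }
  }
  e_par <- sum(E * probe$axis)
  tibble::tibble(frame = fi, Ex = E[1], Ey = E[2], Ez = E[3],
                 E = sqrt(sum(E^2)), E_parallel = e_par)
}

#' Per-frame solvent fields over a trajectory
#'
#' Applies [solvent_field()] to every frame and labels the samples with the
#' trajectory temperature.
#'
#' @param traj A trajectory tibble.
#' @param probe A [c2_probe()]; defaults to the probe of the trajectory's
#'   own solute.
#' @param multipoles Passed to [solvent_field()].
#' @return Tibble with columns `frame`, `temperature`, `Ex`, `Ey`, `Ez`,
#'   `E`, `E_parallel` (MV/cm).
#' @export
solvent_fields <- function(traj, probe = NULL, multipoles = NULL) {
  if (is.null(probe)) {
    sol <- attr(traj, "solute")
    if (is.null(sol)) stop("no probe supplied and trajectory has no solute",
                           call. = FALSE)
    probe <- c2_probe(sol)
  }
  temp <- attr(traj, "temperature")
  if (is.null(temp)) temp <- NA_real_
  if (is.null(multipoles)) {
    # fast vectorised path: point charges only
    w <- traj[traj$species == "water" & traj$charge != 0, ]
    r0 <- probe$point
    dx <- r0[1] - w$x; dy <- r0[2] - w$y; dz <- r0[3] - w$z
    r2 <- dx^2 + dy^2 + dz^2
    if (any(r2 < 1e-12)) {
      stop(sprintf("field singularity in frame %d: water site coincides ",
                   w$frame[which(r2 < 1e-12)[1]]),
           "with the probe point", call. = FALSE)
    }
    k <- field_constant()
    r3 <- r2^1.5
    out <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(frame = w$frame,
                                     ex = k * w$charge * dx / r3,
                                     ey = k * w$charge * dy / r3,
                                     ez = k * w$charge * dz / r3),
                      .data$frame),
      Ex = sum(.data$ex), Ey = sum(.data$ey), Ez = sum(.data$ez),
      .groups = "drop")
    out <- dplyr::mutate(out,
                         E = sqrt(.data$Ex^2 + .data$Ey^2 + .data$Ez^2),
                         E_parallel = .data$Ex * probe$axis[1] +
                           .data$Ey * probe$axis[2] + .data$Ez * probe$axis[3])
  } else {
    out <- dplyr::bind_rows(lapply(trajectory_split(traj), solvent_field,
                                   probe = probe, multipoles = multipoles))
  }
  dplyr::mutate(out, temperature = temp, .after = "frame")
}

#' Read per-site water multipoles from YAML
#'
#' Expects a list `sites` of entries `site`, `mu` (length-3, e Angstrom,
#' body frame) and optionally `Q` (row-major length-9 traceless symmetric,
#' e Angstrom^2).
#'
#' @param file YAML file path.
#' @return Tibble usable as the `multipoles` argument of [solvent_field()].
#' @export
read_multipoles <- function(file) {
  raw <- yaml::read_yaml(file)
  dplyr::bind_rows(lapply(raw$sites, function(s) {
    row <- tibble::tibble(site = s$site, mux = s$mu[1], muy = s$mu[2],
                          muz = s$mu[3])
    if (!is.null(s$Q)) {
      Q <- matrix(as.numeric(s$Q), 3, 3, byrow = TRUE)
      if (abs(sum(diag(Q))) > 1e-9) {
        stop(sprintf("multipole site '%s': quadrupole is not traceless",
                     s$site), call. = FALSE)
      }
      row <- dplyr::mutate(row, Qxx = Q[1, 1], Qxy = Q[1, 2], Qxz = Q[1, 3],
                           Qyy = Q[2, 2], Qyz = Q[2, 3], Qzz = Q[3, 3])
    }
    row
  }))
}
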
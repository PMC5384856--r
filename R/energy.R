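#' Potential energy of a frame
#'
#' Total interaction energy of one configuration: water-water and
#' water-solute Lennard-Jones (oxygen centres, Lorentz-Berthelot mixing
#' against per-atom solute parameters) plus Coulomb over all charged sites.
#' In a cubic periodic cell the minimum-image convention is applied per
#' molecule (a water is imaged as a unit relative to the partner water's
#' oxygen, or relative to the solute), and molecule pairs beyond `cutoff`
#' (oxygen-oxygen distance) are skipped. In a droplet all pairs interact.
#'
#' This is a reference implementation kept independent of the compiled
#' Monte-Carlo sampler; the two are cross-checked in the test suite.
#'
#' @param frame A single-frame tibble in site-record form
#'   (see [frame_from_waters()]).
#' @param cell A [simulation_cell()].
#' @param model Water model supplying the oxygen LJ parameters.
#' @param solute Solute geometry supplying per-atom LJ parameters; required
#'   when the frame contains solute rows.
#' @param cutoff Molecule-based cutoff for periodic cells, Angstrom.
#' @return Energy in kJ/mol.
#' @export
potential_energy <- function(frame, cell, model = water_model(),
                             solute = NULL, cutoff = 9) {
  stopifnot(inherits(cell, "simulation_cell"))
  if (length(unique(frame$frame)) > 1L) {
    stop("`frame` must contain a single frame", call. = FALSE)
  }
  periodic <- cell$kind == "cubic"
  L <- cell$size
  kq <- .coulomb_kJ_mol()
  sig_oo <- model$lennard_jones$sigma
  eps_oo <- model$lennard_jones$epsilon

  w <- frame_water_sites(frame, model)
  nw <- length(unique(w$molecule))
  nsite <- nrow(model$sites)
  # site positions per molecule: nw x nsite x 3
  opos <- if (nw > 0) w$pos[seq(1, nw * nsite, by = nsite), , drop = FALSE]
          else matrix(0, 0, 3)
  qsite <- model$sites$charge

  total <- 0
  min_d2 <- Inf

  if (nw >= 2) {
    for (i in seq_len(nw - 1)) {
      pi_ <- w$pos[((i - 1) * nsite + 1):(i * nsite), , drop = FALSE]
      for (j in (i + 1):nw) {
        shift <- c(0, 0, 0)
        doo <- opos[i, ] - opos[j, ]
        if (periodic) {
          shift <- round(doo / L) * L
          doo <- doo - shift
        }
        r2oo <- sum(doo^2)
        min_d2 <- min(min_d2, r2oo)
        if (periodic && r2oo > cutoff^2) next
        # LJ on oxygens
        sr6 <- (sig_oo^2 / r2oo)^3
        total <- total + 4 * eps_oo * (sr6^2 - sr6)
        # Coulomb over charged site pairs, molecule j imaged as a unit
        pj <- sweep(w$pos[((j - 1) * nsite + 1):(j * nsite), , drop = FALSE],
                    2, shift, "+")
        for (a in seq_len(nsite)) {
          if (qsite[a] == 0) next
          d2 <- (pj[, 1] - pi_[a, 1])^2 + (pj[, 2] - pi_[a, 2])^2 +
            (pj[, 3] - pi_[a, 3])^2
          min_d2 <- min(min_d2, min(d2[qsite != 0]))
          nz <- qsite != 0
          total <- total + kq * qsite[a] * sum(qsite[nz] / sqrt(d2[nz]))
        }
      }
    }
  }

  srows <- frame[frame$species == "solute", ]
  if (nrow(srows) > 0) {
    if (is.null(solute)) {
      stop("frame contains solute rows; supply `solute` for LJ parameters",
           call. = FALSE)
    }
    at <- solute$atoms[match(srows$site, solute$atoms$label), ]
    spos <- cbind(srows$x, srows$y, srows$z)
    sq <- srows$charge
    sp <- solute_atom_position(solute, solute$probe_atoms$P)
    for (i in seq_len(nw)) {
      shift <- c(0, 0, 0)
      if (periodic) {
        shift <- -round((opos[i, ] - sp) / L) * L
      }
      pi_ <- sweep(w$pos[((i - 1) * nsite + 1):(i * nsite), , drop = FALSE],
                   2, shift, "+")
      # LJ: water oxygen vs every solute atom
      d2o <- (spos[, 1] - pi_[1, 1])^2 + (spos[, 2] - pi_[1, 2])^2 +
        (spos[, 3] - pi_[1, 3])^2
      if (periodic && min(d2o) > cutoff^2) next
      sig <- (at$sigma + sig_oo) / 2
      eps <- sqrt(at$epsilon * eps_oo)
      sr6 <- (sig^2 / d2o)^3
      total <- total + sum(4 * eps * (sr6^2 - sr6))
      # Coulomb: charged water sites vs solute charges
      for (a in seq_len(nsite)) {
        if (qsite[a] == 0) next
        d2 <- (spos[, 1] - pi_[a, 1])^2 + (spos[, 2] - pi_[a, 2])^2 +
          (spos[, 3] - pi_[a, 3])^2
        min_d2 <- min(min_d2, min(d2))
        total <- total + kq * qsite[a] * sum(sq / sqrt(d2))
      }
      min_d2 <- min(min_d2, min(d2o))
    }
  }

  if (is.finite(min_d2) && min_d2 < 1e-12) {
    stop("singular energy: coincident interaction sites", call. = FALSE)
  }
  total
}
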
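# Excitation dosimetry: photon energetics of the OH-stretch pump, the
# fraction of excited water molecules in the pumped volume, and the
# temperature jump of the hot ground state after full thermalisation.

.photon_J <- function(wavenumber) {
  .PLANCK_H * .SPEED_OF_LIGHT * wavenumber * 100
}

#' Photon energy of a mid-infrared pump
#'
#' `E = h c nu_tilde`, reported per photon and per mole.
#'
#' @param wavenumber Wavenumber, cm^-1 (> 0).
#' @return One-row tibble: `wavenumber`, `energy_J`, `energy_kJ_mol`.
#' @examples
#' photon_energy(3450)  # ~6.85e-20 J, ~41.3 kJ/mol
#' @export
photon_energy <- function(wavenumber) {
  if (!is.numeric(wavenumber) || any(wavenumber <= 0)) {
    stop("wavenumber must be positive", call. = FALSE)
  }
  eJ <- .photon_J(wavenumber)
  tibble::tibble(wavenumber = wavenumber, energy_J = eJ,
                 energy_kJ_mol = eJ * .AVOGADRO / 1000)
}

#' Excitation geometry
#'
#' Pump-pulse and sample parameters of one pump-probe experiment. Exactly
#' one of `penetration_depth_um` or `absorption_coefficient_cm` (decadic,
#' cm^-1) must be given; the beam is treated as a flat-top disc of the
#' stated diameter.
#'
#' @param pulse_energy_uJ Pump pulse energy, microjoule.
#' @param spot_diameter_um Spot diameter on the sample, micrometre
#'   (flat-top).
#' @param pump_wavenumber Pump centre, cm^-1.
#' @param water_concentration_M Water concentration, mol/L.
#' @param penetration_depth_um 1/e optical penetration depth, micrometre.
#' @param absorption_coefficient_cm Decadic absorption coefficient, cm^-1
#'   (alternative to the depth; depth = 1/(ln 10 * a)).
#' @param convention `"absorbed_in_one_depth"` counts only the photons
#'   absorbed within one penetration depth (factor 1 - 1/e);
#'   `"incident"` counts all incident photons.
#' @return Object of class `excitation_geometry`.
#' @export
excitation_geometry <- function(pulse_energy_uJ, spot_diameter_um,
                                pump_wavenumber, water_concentration_M,
                                penetration_depth_um = NULL,
                                absorption_coefficient_cm = NULL,
                                convention = c("absorbed_in_one_depth",
                                               "incident")) {
  convention <- match.arg(convention)
  vals <- c(pulse_energy_uJ, spot_diameter_um, pump_wavenumber,
            water_concentration_M)
  if (any(!is.finite(vals)) || any(vals < 0) || pump_wavenumber <= 0 ||
      spot_diameter_um <= 0 || water_concentration_M <= 0) {
    stop("all physical quantities must be positive", call. = FALSE)
  }
  if (is.null(penetration_depth_um) == is.null(absorption_coefficient_cm)) {
    stop("give exactly one of penetration_depth_um or ",
         "absorption_coefficient_cm", call. = FALSE)
  }
  if (is.null(penetration_depth_um)) {
    penetration_depth_um <- 1 / (log(10) * absorption_coefficient_cm) * 1e4
  }
  if (penetration_depth_um <= 0) {
    stop("penetration depth must be positive", call. = FALSE)
  }
  structure(list(pulse_energy_uJ = pulse_energy_uJ,
                 spot_diameter_um = spot_diameter_um,
                 pump_wavenumber = pump_wavenumber,
                 water_concentration_M = water_concentration_M,
                 penetration_depth_um = penetration_depth_um,
                 convention = convention),
            class = "excitation_geometry")
}

#' Fraction of excited water molecules
#'
#' Photons (incident, or absorbed within one penetration depth depending
#' on the geometry's convention) divided by the number of water molecules
#' in the pumped cylinder (spot area times penetration depth), assuming
#' one OH-stretch quantum per excited molecule.
#'
#' @param geom An [excitation_geometry()].
#' @return Excited fraction (dimensionless). A fraction >= 1 raises a
#'   saturation warning.
#' @export
excited_fraction <- function(geom) {
  stopifnot(inherits(geom, "excitation_geometry"))
  photons <- geom$pulse_energy_uJ * 1e-6 / .photon_J(geom$pump_wavenumber)
  if (geom$convention == "absorbed_in_one_depth") {
    photons <- photons * (1 - exp(-1))
  }
  volume_L <- pi * (geom$spot_diameter_um / 2 * 1e-6)^2 *
    (geom$penetration_depth_um * 1e-6) * 1000  # m^3 -> L
  molecules <- geom$water_concentration_M * .AVOGADRO * volume_L
  frac <- photons / molecules
  if (frac >= 1) warning("saturation: excited fraction >= 1")
  frac
}

#' Hot-ground-state temperature jump
#'
#' All deposited vibrational energy is assumed thermalised in the water:
#' `dT = fraction * molar photon energy / molar heat capacity`.
#'
#' @param fraction Excited fraction in \[0, 1).
#' @param wavenumber Pump wavenumber, cm^-1.
#' @param heat_capacity Molar heat capacity of water, J/(mol K); default
#'   75.3.
#' @return Temperature increase, K.
#' @examples
#' temperature_jump(0.04, 3450)  # ~22 K
#' @export
temperature_jump <- function(fraction, wavenumber, heat_capacity = 75.3) {
  if (any(fraction < 0) || any(fraction >= 1)) {
    stop("fraction must lie in [0, 1)", call. = FALSE)
  }
  fraction * .photon_J(wavenumber) * .AVOGADRO / heat_capacity
}

#' Optical penetration depth from decadic absorptivity
#'
#' `depth = 1 / (ln 10 * epsilon * c)`, converted to micrometre.
#'
#' @param epsilon Decadic molar absorptivity, L/(mol cm).
#' @param concentration mol/L.
#' @return Depth, micrometre.
#' @export
penetration_depth <- function(epsilon, concentration) {
  if (any(epsilon <= 0) || any(concentration <= 0)) {
    stop("epsilon and concentration must be positive", call. = FALSE)
  }
  1 / (log(10) * epsilon * concentration) * 1e4
}

#' Dosimetry report
#'
#' Photon energy, excited fraction and temperature jump for one
#' excitation geometry.
#'
#' @param geom An [excitation_geometry()].
#' @param heat_capacity J/(mol K), default 75.3.
#' @return One-row tibble: `energy_J`, `energy_kJ_mol`, `fraction`,
#'   `delta_T_K`, `convention`.
#' @export
dosimetry_report <- function(geom, heat_capacity = 75.3) {
  pe <- photon_energy(geom$pump_wavenumber)
  fr <- excited_fraction(geom)
  tibble::tibble(energy_J = pe$energy_J, energy_kJ_mol = pe$energy_kJ_mol,
                 fraction = fr,
                 delta_T_K = temperature_jump(fr, geom$pump_wavenumber,
                                              heat_capacity),
                 convention = geom$convention)
}
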
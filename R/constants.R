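# Physical constants (CODATA 2018) and the unit-bridging factors used
# throughout: coordinates in Angstrom, charges in e, energies in kJ/mol,
# electric fields in MV/cm.

.ELEMENTARY_CHARGE <- 1.602176634e-19        # C
.COULOMB_K <- 8.9875517873681764e9           # 1/(4 pi eps0), N m^2 C^-2
.PLANCK_H <- 6.62607015e-34                  # J s
.SPEED_OF_LIGHT <- 2.99792458e8              # m/s
.AVOGADRO <- 6.02214076e23                   # 1/mol
.KB_KJ_MOL <- 0.008314462618                 # kJ/(mol K)

#' Electric-field conversion constant
#'
#' Field of a +1 e point charge at 1 Angstrom, expressed in MV/cm.
#' Multiplying `q / r^2` (e, Angstrom) by this constant gives the Coulomb
#' field in MV/cm.
#'
#' @return A single number, MV/cm per (e/Angstrom^2).
#' @export
field_constant <- function() {
  # q/(4 pi eps0 r^2): C * N m^2 C^-2 / m^2 -> V/m; 1 MV/cm = 1e8 V/m
  .COULOMB_K * .ELEMENTARY_CHARGE / 1e-20 / 1e8
}

# Coulomb energy prefactor: kJ/mol for q1*q2/r in (e, e, Angstrom)
.coulomb_kJ_mol <- function() {
  .COULOMB_K * .ELEMENTARY_CHARGE^2 / 1e-10 * .AVOGADRO / 1000
}
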
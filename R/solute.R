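#' Load a rigid solute geometry
#'
#' Reads a solute parameter file: atom labels, positions, partial charges
#' and Lennard-Jones parameters, plus the designation of the phosphate P,
#' O1 and O2 atoms used to construct the field probe. The packaged default
#' is a rigid gauche-gauche dimethylphosphate (DMP) anion with united-atom
#' methyl groups and a synthetic charge set constrained to net -1 e (the
#' original ESP-derived charges are not public data shipped here).
#'
#' @param file Path to a YAML solute file; defaults to the packaged
#'   synthetic gauche-gauche DMP.
#' @return An object of class `solute_geometry`: list with `name`, `atoms`
#'   (tibble: `label`, `x`, `y`, `z`, `charge`, `sigma`, `epsilon`) and
#'   `probe_atoms` (labels of P, O1, O2).
#' @examples
#' s <- dmp_solute()
#' sum(s$atoms$charge)  # -1: the phosphate carries one negative charge
#' @export
dmp_solute <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "dmp_gg_synthetic.yaml",
                        package = "shellfield")
  }
  raw <- yaml::read_yaml(file)
  atoms <- dplyr::bind_rows(lapply(raw$atoms, tibble::as_tibble))
  pa <- raw$probe_atoms
  labs <- unlist(pa[c("P", "O1", "O2")])
  if (!all(labs %in% atoms$label) || anyDuplicated(labs)) {
    stop("solute must designate distinct P, O1, O2 atoms present in `atoms`",
         call. = FALSE)
  }
  net <- sum(atoms$charge)
  if (abs(net + 1) > 1e-6) {
    stop(sprintf("DMP solute must carry net charge -1 e (got %.6f)", net),
         call. = FALSE)
  }
  structure(list(name = raw$name, atoms = atoms,
                 probe_atoms = list(P = pa$P, O1 = pa$O1, O2 = pa$O2)),
            class = "solute_geometry")
}

solute_atom_position <- function(solute, label) {
  row <- solute$atoms[solute$atoms$label == label, ]
  c(row$x, row$y, row$z)
}

#' Field probe on the C2 axis of the phosphate group
#'
#' The probe point is the midpoint of the O1-O2 axis of the PO2- group and
#' the projection axis is the C2 symmetry axis: the unit vector from P
#' through that midpoint, pointing away from the phosphorus into the
#' solvent. For a symmetric geometry (|PO1| = |PO2|) the axis is orthogonal
#' to the O1-O2 vector.
#'
#' @param solute A [dmp_solute()] geometry (or any `solute_geometry` with
#'   designated P, O1, O2 atoms).
#' @return An object of class `field_probe`: list with `point` (Angstrom)
#'   and `axis` (unit 3-vector).
#' @examples
#' p <- c2_probe(dmp_solute())
#' sqrt(sum(p$axis^2))  # 1
#' @export
c2_probe <- function(solute) {
  if (!inherits(solute, "solute_geometry")) {
    stop("`solute` must be a solute_geometry object", call. = FALSE)
  }
  P <- solute_atom_position(solute, solute$probe_atoms$P)
  O1 <- solute_atom_position(solute, solute$probe_atoms$O1)
  O2 <- solute_atom_position(solute, solute$probe_atoms$O2)
  r0 <- (O1 + O2) / 2
  v1 <- O1 - P
  v2 <- O2 - P
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(cr^2)) < 1e-9 * sqrt(sum(v1^2)) * sqrt(sum(v2^2))) {
    stop("degenerate geometry: P, O1, O2 are collinear", call. = FALSE)
  }
  axis <- r0 - P
  axis <- axis / sqrt(sum(axis^2))
  structure(list(point = r0, axis = axis), class = "field_probe")
}

#' Simulation cell
#'
#' Either a spherical droplet (hard spherical wall of the given radius,
#' no periodicity) or a cubic periodic box (minimum-image convention in
#' all energy and distance computations).
#'
#' @param kind `"droplet"` or `"cubic"`.
#' @param size Radius (droplet) or edge length (cubic), Angstrom.
#' @return An object of class `simulation_cell`.
#' @export
simulation_cell <- function(kind = c("droplet", "cubic"), size = 14) {
  kind <- match.arg(kind)
  if (!is.numeric(size) || length(size) != 1L || size <= 0) {
    stop("cell size must be a single positive number", call. = FALSE)
  }
  structure(list(kind = kind, size = as.numeric(size)),
            class = "simulation_cell")
}
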
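#' Load a rigid five-site water model
#'
#' Reads a rigid water parameter file (body-frame site offsets, site charges
#' and the oxygen Lennard-Jones parameters). The packaged default is the
#' TIP5P model: a neutral oxygen carrying the Lennard-Jones centre, two
#' positively charged hydrogens and two negatively charged lone-pair sites.
#'
#' @param file Path to a YAML parameter file. Defaults to the packaged
#'   TIP5P file.
#' @return An object of class `water_model`: a list with `name`, `sites`
#'   (tibble with columns `site`, `x`, `y`, `z`, `charge`; Angstrom and e)
#'   and `lennard_jones` (`sigma` in Angstrom, `epsilon` in kJ/mol).
#' @examples
#' m <- water_model()
#' sum(m$sites$charge)  # 0: the molecule is neutral
#' @export
water_model <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "tip5p.yaml", package = "shellfield")
  }
  raw <- yaml::read_yaml(file)
  sites <- dplyr::bind_rows(lapply(raw$sites, tibble::as_tibble))
  if (nrow(sites) != 5L) {
    stop("water model must define exactly 5 sites", call. = FALSE)
  }
  if (abs(sum(sites$charge)) > 1e-9) {
    stop("water model sites must carry zero net charge", call. = FALSE)
  }
  structure(
    list(name = raw$name, sites = sites,
         lennard_jones = list(sigma = raw$lennard_jones$sigma,
                              epsilon = raw$lennard_jones$epsilon)),
    class = "water_model"
  )
}

#' Construct a rigid water state
#'
#' A rigid water molecule is fully described by its oxygen position and a
#' unit quaternion orientation; the site geometry lives in the water model.
#'
#' @param oxygen_position Numeric length-3, oxygen position in Angstrom.
#' @param orientation Unit quaternion (w, x, y, z); defaults to identity.
#' @return An object of class `rigid_water`.
#' @export
rigid_water <- function(oxygen_position, orientation = quat_identity()) {
  stopifnot(is.numeric(oxygen_position), length(oxygen_position) == 3L)
  quat_check(orientation)
  structure(list(oxygen_position = as.numeric(oxygen_position),
                 orientation = as.numeric(orientation)),
            class = "rigid_water")
}

#' World-frame charge sites of a rigid water
#'
#' Rotates the model's body-frame site offsets by the molecule's orientation
#' and translates them to the oxygen position. The rigid geometry (all
#' intra-molecular site distances) is preserved exactly by construction.
#'
#' @param water A [rigid_water()] state.
#' @param model A [water_model()]; defaults to packaged TIP5P.
#' @return Tibble with columns `site`, `x`, `y`, `z`, `charge`.
#' @examples
#' w <- rigid_water(c(0, 0, 0))
#' build_water_sites(w)
#' @export
build_water_sites <- function(water, model = water_model()) {
  if (!inherits(water, "rigid_water")) {
    stop("`water` must be a rigid_water object", call. = FALSE)
  }
  quat_check(water$orientation)
  R <- quat_rotation_matrix(water$orientation)
  body <- as.matrix(model$sites[, c("x", "y", "z")])
  world <- body %*% t(R)
  tibble::tibble(
    site = model$sites$site,
    x = world[, 1] + water$oxygen_position[1],
    y = world[, 2] + water$oxygen_position[2],
    z = world[, 3] + water$oxygen_position[3],
    charge = model$sites$charge
  )
}
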
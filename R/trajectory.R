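# Trajectories are plain tibbles in long "site record" form so they pipe
# straight into dplyr and the analysis verbs. One row per interaction site:
#   frame    integer frame index (1-based)
#   species  "solute" or "water"
#   molecule integer molecule id (0 for the solute)
#   site     site label ("O","H1","H2","L1","L2" or a solute atom label)
#   x, y, z  Angstrom
#   charge   e
# Metadata (temperature, cell, run statistics) travels in attributes.

new_trajectory <- function(df, temperature, cell, solute, model, stats = NULL) {
  out <- tibble::new_tibble(df, class = "shell_trajectory")
  attr(out, "temperature") <- temperature
  attr(out, "cell") <- cell
  attr(out, "solute") <- solute
  attr(out, "water_model") <- model
  attr(out, "stats") <- stats
  out
}

#' Assemble a single frame tibble from rigid waters and an optional solute
#'
#' @param waters List of [rigid_water()] states.
#' @param solute Optional [dmp_solute()] geometry included as `species =
#'   "solute"` rows (molecule id 0).
#' @param model Water model used to expand sites; defaults to TIP5P.
#' @param frame Frame index stored in the `frame` column.
#' @return A tibble in the trajectory site-record form.
#' @export
frame_from_waters <- function(waters, solute = NULL, model = water_model(),
                              frame = 1L) {
  rows <- list()
  if (!is.null(solute)) {
    rows[[1]] <- tibble::tibble(
      frame = as.integer(frame), species = "solute", molecule = 0L,
      site = solute$atoms$label, x = solute$atoms$x, y = solute$atoms$y,
      z = solute$atoms$z, charge = solute$atoms$charge
    )
  }
  wrows <- purrr::imap(waters, function(w, i) {
    s <- build_water_sites(w, model)
    tibble::tibble(frame = as.integer(frame), species = "water",
                   molecule = as.integer(i), site = s$site,
                   x = s$x, y = s$y, z = s$z, charge = s$charge)
  })
  dplyr::bind_rows(c(rows, wrows))
}

# split a trajectory tibble into per-frame tibbles
trajectory_split <- function(traj) {
  split(tibble::as_tibble(traj), traj$frame)
}

# water oxygen coordinates of one frame as a matrix (one row per molecule)
frame_oxygens <- function(frame_df) {
  o <- frame_df[frame_df$species == "water" & frame_df$site == "O", ]
  o <- o[order(o$molecule), ]
  cbind(o$x, o$y, o$z)
}

# all water site coordinates/charges of one frame, ordered by molecule then
# the model site order; returns list(pos = n x 3, charge = n, molecule = n)
frame_water_sites <- function(frame_df, model = water_model()) {
  w <- frame_df[frame_df$species == "water", ]
  site_order <- model$sites$site
  w <- w[order(w$molecule, match(w$site, site_order)), ]
  list(pos = cbind(w$x, w$y, w$z), charge = w$charge, molecule = w$molecule)
}

#' @export
print.shell_trajectory <- function(x, ...) {
  st <- attr(x, "stats")
  cat(sprintf(
    "<shell_trajectory> %d frame(s), %d water(s), T = %s K, cell = %s (%.1f A)\n",
    length(unique(x$frame)),
    length(unique(x$molecule[x$species == "water"])),
    format(attr(x, "temperature")), attr(x, "cell")$kind,
    attr(x, "cell")$size))
  if (!is.null(st)) {
    cat(sprintf("  acceptance fraction %.3f over %d sweeps\n",
                st$acceptance, st$n_sweeps))
  }
  NextMethod()
}
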
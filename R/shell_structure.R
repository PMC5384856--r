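# select site rows of a frame/trajectory tibble by species and site label
select_sites <- function(df, selection) {
  out <- df
  if (!is.null(selection$species)) {
    out <- out[out$species %in% selection$species, ]
  }
  if (!is.null(selection$site)) {
    out <- out[out$site %in% selection$site, ]
  }
  out
}

#' Site selection descriptor
#'
#' @param species `"water"`, `"solute"` or `NULL` (any).
#' @param site Character vector of site labels or `NULL` (any).
#' @return A list usable as `reference`/`target` in [radial_distribution()].
#' @export
site_selection <- function(species = NULL, site = NULL) {
  list(species = species, site = site)
}

analysis_volume <- function(cell) {
  if (cell$kind == "droplet") 4 / 3 * pi * cell$size^3 else cell$size^3
}

#' Radial distribution function between two site selections
#'
#' Standard shell-volume-normalised pair histogram, averaged over frames
#' and reference sites. The target number density uses the mean target
#' count per frame within the analysis volume (droplet volume or periodic
#' box volume). In a periodic cell distances use the minimum image and
#' `r_max` must not exceed half the box edge; in a droplet `r_max` must not
#' exceed the diameter.
#'
#' @param traj Trajectory tibble.
#' @param reference,target [site_selection()] descriptors, e.g. the free
#'   phosphate oxygens vs the water oxygens.
#' @param r_max Histogram range, Angstrom.
#' @param n_bins Number of bins.
#' @param cell Simulation cell; defaults to the trajectory's own.
#' @return A tibble of class `radial_distribution` with columns `r` (bin
#'   centre), `g`, `count`; attributes `edges`, `n_frames`, `density`.
#' @export
radial_distribution <- function(traj, reference, target, r_max = 8,
                                n_bins = 80, cell = NULL) {
  if (is.null(cell)) cell <- attr(traj, "cell")
  if (is.null(cell)) stop("no simulation cell available; pass `cell`",
                          call. = FALSE)
  if (r_max <= 0) stop("r_max must be positive", call. = FALSE)
  if (cell$kind == "cubic" && r_max > cell$size / 2) {
    stop("geometry error: r_max exceeds half the periodic box edge",
         call. = FALSE)
  }
  if (cell$kind == "droplet" && r_max > 2 * cell$size) {
    stop("geometry error: r_max exceeds the droplet diameter", call. = FALSE)
  }
  edges <- seq(0, r_max, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  frames <- trajectory_split(traj)
  n_ref_tot <- 0
  n_tgt_tot <- 0
  L <- cell$size
  for (fd in frames) {
    ref <- select_sites(fd, reference)
    tgt <- select_sites(fd, target)
    if (nrow(ref) == 0 || nrow(tgt) == 0) {
      stop("selection error: empty reference or target selection",
           call. = FALSE)
    }
    n_ref_tot <- n_ref_tot + nrow(ref)
    n_tgt_tot <- n_tgt_tot + nrow(tgt)
    for (i in seq_len(nrow(ref))) {
      dx <- tgt$x - ref$x[i]; dy <- tgt$y - ref$y[i]; dz <- tgt$z - ref$z[i]
      if (cell$kind == "cubic") {
        dx <- dx - round(dx / L) * L
        dy <- dy - round(dy / L) * L
        dz <- dz - round(dz / L) * L
      }
      d <- sqrt(dx^2 + dy^2 + dz^2)
      # drop the self pair if reference and target overlap
      d <- d[d > 1e-9 & d < r_max]
      if (length(d)) {
        counts <- counts + tabulate(findInterval(d, edges,
                                                 rightmost.closed = TRUE),
                                    nbins = n_bins)
      }
    }
  }
  nf <- length(frames)
  rho <- (n_tgt_tot / nf) / analysis_volume(cell)
  shell <- 4 / 3 * pi * diff(edges^3)
  g <- counts / ((n_ref_tot / nf) * nf * rho * shell)
  out <- tibble::new_tibble(
    tibble::tibble(r = (edges[-1] + edges[-length(edges)]) / 2, g = g,
                   count = counts),
    class = "radial_distribution")
  attr(out, "edges") <- edges
  attr(out, "n_frames") <- nf
  attr(out, "density") <- rho
  out
}

#' First-shell coordination number
#'
#' Mean number of target sites within `r_cut` of a reference site,
#' averaged over frames and reference sites (the integral of the pair
#' histogram up to the first-minimum cutoff).
#'
#' @inheritParams radial_distribution
#' @param r_cut First-minimum cutoff, Angstrom.
#' @return A single number (waters per reference site).
#' @export
first_shell_occupancy <- function(traj, reference, target, r_cut = 3.5,
                                  cell = NULL) {
  if (is.null(cell)) cell <- attr(traj, "cell")
  frames <- trajectory_split(traj)
  tot <- 0
  nref <- 0
  for (fd in frames) {
    ref <- select_sites(fd, reference)
    tgt <- select_sites(fd, target)
    for (i in seq_len(nrow(ref))) {
      dx <- tgt$x - ref$x[i]; dy <- tgt$y - ref$y[i]; dz <- tgt$z - ref$z[i]
      if (!is.null(cell) && cell$kind == "cubic") {
        L <- cell$size
        dx <- dx - round(dx / L) * L
        dy <- dy - round(dy / L) * L
        dz <- dz - round(dz / L) * L
      }
      d2 <- dx^2 + dy^2 + dz^2
      tot <- tot + sum(d2 > 1e-18 & d2 <= r_cut^2)
      nref <- nref + 1
    }
  }
  tot / nref
}

#' Normalised distribution of projected field amplitudes
#'
#' Histogram of the C2-projected field samples of one temperature,
#' normalised to unit total occurrence. The bin-free sample mean and
#' standard deviation are carried in attributes (and reported by
#' `summary()`), so the distribution mean never suffers binning error.
#'
#' @param samples Tibble of field samples (from [solvent_fields()]) with
#'   columns `E_parallel` and `temperature`; all rows must share one
#'   temperature.
#' @param binwidth Bin width, MV/cm (default 2).
#' @param edges Optional explicit bin edges overriding `binwidth`.
#' @return Tibble of class `field_distribution` with columns `bin_lo`,
#'   `bin_hi`, `bin_center`, `occurrence`; attributes `temperature`, `n`,
#'   `mean`, `sd`, `samples`.
#' @export
field_distribution <- function(samples, binwidth = 2, edges = NULL) {
  if (nrow(samples) < 1) stop("at least one field sample required",
                              call. = FALSE)
  temps <- unique(samples$temperature)
  temps <- temps[!is.na(temps)]
  if (length(temps) > 1) {
    stop("mixed temperatures in field samples: ",
         paste(temps, collapse = ", "), call. = FALSE)
  }
  v <- samples$E_parallel
  if (is.null(edges)) {
    lo <- floor(min(v) / binwidth) * binwidth
    hi <- ceiling(max(v) / binwidth) * binwidth
    if (hi <= lo) hi <- lo + binwidth
    edges <- seq(lo, hi, by = binwidth)
  }
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  out <- tibble::new_tibble(
    tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                   bin_center = (edges[-1] + edges[-length(edges)]) / 2,
                   occurrence = counts / length(v)),
    class = "field_distribution")
  attr(out, "temperature") <- if (length(temps)) temps else NA_real_
  attr(out, "n") <- length(v)
  attr(out, "mean") <- mean(v)
  attr(out, "sd") <- stats::sd(v)
  attr(out, "samples") <- v
  out
}

#' @export
summary.field_distribution <- function(object, ...) {
  tibble::tibble(temperature = attr(object, "temperature"),
                 n = attr(object, "n"), mean = attr(object, "mean"),
                 sd = attr(object, "sd"))
}

check_same_grid <- function(d1, d2) {
  e1 <- c(d1$bin_lo, d1$bin_hi[nrow(d1)])
  e2 <- c(d2$bin_lo, d2$bin_hi[nrow(d2)])
  if (length(e1) != length(e2) || max(abs(e1 - e2)) > 1e-9) {
    stop("grid error: field distributions are binned on different edges; ",
         "rebin with shared `edges` (no silent rebinning)", call. = FALSE)
  }
}

# parabolic refinement of a grid extremum at index i
refine_extremum <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (abs(denom) < 1e-15) return(x[i])
  x[i] + 0.5 * (y[i - 1] - y[i + 1]) / denom * (x[i + 1] - x[i])
}

#' Occurrence difference of two field distributions
#'
#' Per-bin difference `d_high - d_low` of two normalised distributions on
#' a shared grid. Because both inputs are normalised, the differences sum
#' to zero exactly. The locations of the differential extrema (parabolic
#' refinement of the grid extrema) and their separation are stored in
#' attributes.
#'
#' @param d_high,d_low [field_distribution()] objects on identical edges
#'   (high- and low-temperature, respectively).
#' @return Tibble of class `occurrence_difference` with `bin_center`,
#'   `difference`; attributes `temperatures`, `extrema` (locations,
#'   MV/cm), `separation` (MV/cm).
#' @export
occurrence_difference <- function(d_high, d_low) {
  check_same_grid(d_high, d_low)
  diffv <- d_high$occurrence - d_low$occurrence
  out <- tibble::new_tibble(
    tibble::tibble(bin_center = d_high$bin_center, difference = diffv),
    class = "occurrence_difference")
  imax <- which.max(diffv)
  imin <- which.min(diffv)
  xmax <- refine_extremum(d_high$bin_center, diffv, imax)
  xmin <- refine_extremum(d_high$bin_center, diffv, imin)
  attr(out, "temperatures") <- c(high = attr(d_high, "temperature"),
                                 low = attr(d_low, "temperature"))
  attr(out, "extrema") <- c(maximum = xmax, minimum = xmin)
  attr(out, "separation") <- abs(xmax - xmin)
  out
}

#' Mean-field change between two distributions
#'
#' Signed difference of the (bin-free) sample means, `mean(d1) - mean(d2)`,
#' with a seeded bootstrap standard error. For distributions labelled by
#' temperature, calling with (high, low) gives the temperature-induced
#' change of the mean projected field.
#'
#' @param d1,d2 [field_distribution()] objects.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return One-row tibble: `delta_mean` (MV/cm), `se` (bootstrap standard
#'   error), `n1`, `n2`.
#' @export
mean_field_change <- function(d1, d2, n_boot = 1000, seed = 1) {
  s1 <- attr(d1, "samples")
  s2 <- attr(d2, "samples")
  delta <- mean(s1) - mean(s2)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(s1, replace = TRUE)) - mean(sample(s2, replace = TRUE))
  }, numeric(1))
  tibble::tibble(delta_mean = delta, se = stats::sd(boots),
                 n1 = length(s1), n2 = length(s2))
}

#' Block-averaged standard error of the mean projected field
#'
#' Autocorrelation-aware error estimate: the samples are cut into
#' contiguous blocks and the standard error of the block means is
#' reported.
#'
#' @param samples Field-sample tibble with an `E_parallel` column.
#' @param n_blocks Number of blocks (default 10).
#' @return One-row tibble: `mean`, `se_block`, `n_blocks`.
#' @export
block_error <- function(samples, n_blocks = 10) {
  v <- samples$E_parallel
  blk <- split(v, cut(seq_along(v), n_blocks, labels = FALSE))
  bm <- vapply(blk, mean, numeric(1))
  tibble::tibble(mean = mean(v), se_block = stats::sd(bm) / sqrt(n_blocks),
                 n_blocks = n_blocks)
}
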
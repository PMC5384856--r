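# Unit-quaternion helpers for rigid-body orientations. Quaternions are
# length-4 numeric vectors (w, x, y, z); rotations act on body-frame
# coordinates to produce world-frame coordinates.

quat_norm <- function(q) sqrt(sum(q^2))

quat_check <- function(q, tol = 1e-9) {
  if (length(q) != 4L || !is.numeric(q) || any(!is.finite(q))) {
    stop("orientation must be a finite numeric quaternion (w, x, y, z)",
         call. = FALSE)
  }
  if (abs(quat_norm(q) - 1) > tol) {
    stop(sprintf("quaternion normalization failure: |q| = %.12f", quat_norm(q)),
         call. = FALSE)
  }
  invisible(q)
}

quat_identity <- function() c(1, 0, 0, 0)

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# 3x3 rotation matrix of a unit quaternion
quat_rotation_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# random uniform unit quaternion (Shoemake), uses the R RNG stream
quat_random_uniform <- function() {
  u <- stats::runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}
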
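#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kinetic fit
#'
#' One row per model parameter with its estimate and 1-sigma standard
#' error.
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std_error`.
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  x$parameters
}

#' One-row summary of a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return Tibble: `form`, `sigma` (residual RMS, mOD), `converged`,
#'   `ill_conditioned`, `n`.
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(form = x$form, sigma = x$sigma, converged = x$converged,
                 ill_conditioned = x$ill_conditioned, n = x$n)
}
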
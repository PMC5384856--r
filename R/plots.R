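# Quick-look ggplot2 graphics for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.radial_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "g(r)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.field_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center,
                                       y = .data$occurrence)) +
    ggplot2::geom_col(width = diff(object$bin_lo[1:2]), fill = "steelblue") +
    ggplot2::labs(x = "E∥ (MV/cm)", y = "occurrence",
                  title = sprintf("T = %s K", attr(object, "temperature")))
}

#' @exportS3Method ggplot2::autoplot
autoplot.occurrence_difference <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center,
                                       y = .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "E∥ (MV/cm)", y = "occurrence difference")
}

#' @exportS3Method ggplot2::autoplot
autoplot.difference_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$nu, y = .data$dA)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(nu ~ (cm^-1)), y = expression(Delta * A))
}

#' @exportS3Method ggplot2::autoplot
autoplot.transient_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delay_ps,
                                       y = .data$dA_mOD)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "delay (ps)", y = expression(Delta * A ~ (mOD)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.kinetic_fit <- function(object, ...) {
  if (is.data.frame(object$data)) {
    df <- tibble::tibble(delay_ps = object$data$delay_ps,
                         dA_mOD = object$data$dA_mOD,
                         fitted = object$fitted)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$delay_ps)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$dA_mOD), size = 0.8) +
      ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "delay (ps)", y = expression(Delta * A ~ (mOD)))
  } else {
    stop("autoplot for global fits is not implemented; plot traces ",
         "individually", call. = FALSE)
  }
}
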
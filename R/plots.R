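# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sagittal surface profile
#' @param object an `apdi_profile`.
#' @param ... further profiles to overlay (named arguments become legend
#'   labels).
#' @return a ggplot.
#' @export
autoplot.apdi_profile <- function(object, ...) {
  extras <- list(...)
  extras <- extras[vapply(extras, inherits, TRUE, "apdi_profile")]
  d <- dplyr::bind_rows(c(list(profile = tibble::as_tibble(object)),
                          lapply(extras, tibble::as_tibble)),
                        .id = "curve")
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(-2, 0, 2), linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "scan position x (mm, + posterior)",
                  y = "height (mm)") +
    ggplot2::theme_minimal()
}

#' Plot sensitivity sweeps
#' @param object an `apdi_sensitivity`.
#' @param output which outputs to show.
#' @param ... unused.
#' @return a ggplot (output value vs input, faceted by parameter).
#' @export
autoplot.apdi_sensitivity <- function(object,
                                      output = c("AD", "CPR", "AR"), ...) {
  d <- tidyr::pivot_longer(object$records, cols = dplyr::all_of(output),
                           names_to = "output", values_to = "val")
  ggplot2::ggplot(d, ggplot2::aes(.data$value, .data$val)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(output ~ param, scales = "free") +
    ggplot2::labs(x = "input value", y = "output value") +
    ggplot2::theme_minimal()
}

#' Plot random-sampling scatter with R-squared labels
#' @param object an `apdi_sampling`.
#' @param output one of "AD", "CPR", "AR".
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.apdi_sampling <- function(object, output = "AD", ...) {
  inputs <- c("mu", "thk", "iop", "mu_post", "al", "el")
  d <- tidyr::pivot_longer(object$records, cols = dplyr::all_of(inputs),
                           names_to = "input", values_to = "x")
  lab <- object$r_squared[object$r_squared$output == output &
                            object$r_squared$input %in% inputs, ]
  lab$label <- sprintf("R^2 == %.2f", lab$r_squared)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data[[output]])) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~input, scales = "free_x") +
    ggplot2::geom_text(data = lab, parse = TRUE,
                       ggplot2::aes(x = -Inf, y = Inf, label = .data$label),
                       hjust = -0.1, vjust = 1.5, inherit.aes = FALSE) +
    ggplot2::labs(x = "input value", y = output) +
    ggplot2::theme_minimal()
}

#' Plot an inverse fit: measured vs predicted AD over IOP
#' @param object an `apdi_inverse_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.apdi_inverse_fit <- function(object, ...) {
  d <- object$predictions
  ggplot2::ggplot(d, ggplot2::aes(.data$iop_mmhg)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$ad_meas), shape = 15, size = 3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ad_pred)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$ad_pred), shape = 1, size = 3) +
    ggplot2::labs(x = "IOP (mmHg)", y = "apex displacement (mm)",
                  title = sprintf("mu = %.4f MPa, RMSE = %.3f mm",
                                  object$mu_hat, object$rmse)) +
    ggplot2::theme_minimal()
}
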
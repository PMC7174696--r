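# ggplot2 methods for the package's result types.

#' Plot a culture series
#'
#' Faceted concentration-versus-time panels for biomass and the tracked
#' metabolites.
#'
#' @param object A `culture_series` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.culture_series <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "variable", values_to = "mM")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$mM)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (mM)") +
    ggplot2::theme_minimal()
}

#' Plot the polar mode cloud
#'
#' First two angle coordinates of every mode, shaded by module; overlay an
#' experimental point with `exp`.
#'
#' @param object An `em_polar` tibble from [polar_coords()].
#' @param exp Optional `experimental_point`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.em_polar <- function(object, exp = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$theta1, y = .data$theta2,
                                    color = .data$lam)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_color_viridis_c(name = expression(lambda)) +
    ggplot2::coord_cartesian(xlim = c(0, 90), ylim = c(0, 90)) +
    ggplot2::labs(x = expression(theta[1] ~ "(deg)"),
                  y = expression(theta[2] ~ "(deg)")) +
    ggplot2::theme_minimal()
  if (!is.null(exp)) {
    p <- p + ggplot2::annotate("point", x = exp$phi[1], y = exp$phi[2],
                               color = "red", size = 3, shape = 17)
  }
  p
}

#' Plot a perturbation path
#'
#' Target yield fold change along the walk.
#'
#' @param object A `perturbation_path`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perturbation_path <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$step, y = .data$fold_change)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "step", y = "target yield fold change") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
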
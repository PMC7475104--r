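#' Plot a component spectrum
#'
#' @param object A `component_spectrum` or `scatter_spectrum`.
#' @param windows Optionally shade the acquisition windows (pass `NULL` to
#'   omit).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot component_spectrum
#' @export
autoplot.component_spectrum <- function(object, windows = default_windows(),
                                        ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$energy_kev, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Energy (keV)", y = "Counts / s / MBq / keV")
  if (!is.null(windows)) {
    p <- p + ggplot2::geom_rect(
      data = windows, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$lo_kev, xmax = .data$hi_kev,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.12, fill = "steelblue")
  }
  p
}

#' @rdname autoplot.component_spectrum
#' @method autoplot scatter_spectrum
#' @export
autoplot.scatter_spectrum <- function(object, windows = default_windows(),
                                      ...) {
  autoplot.component_spectrum(object, windows, ...) +
    ggplot2::labs(y = "Relative counts / keV")
}

#' Plot estimated vs true time-activity curves
#'
#' @param object A [quantify_study()] result with truth columns.
#' @param ... Unused.
#' @return A ggplot faceted by ROI and isotope: points are estimates, lines
#'   the Bateman ground truth.
#' @method autoplot study_estimates
#' @export
autoplot.study_estimates <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(tibble::as_tibble(object), .data$label, .data$time_d,
                     isotope = "Th227", est = .data$a_th227,
                     true = .data$true_a_th227),
    dplyr::transmute(tibble::as_tibble(object), .data$label, .data$time_d,
                     isotope = "Ra223", est = .data$a_ra223,
                     true = .data$true_a_ra223))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_d)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$true), linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$est)) +
    ggplot2::facet_grid(isotope ~ label, scales = "free_y") +
    ggplot2::labs(x = "Days since fill", y = "Activity (MBq)")
}
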
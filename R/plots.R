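# ggplot2 visualisations for fitted objects and traces.

#' @rdname fit_order
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  ylab <- switch(as.character(object$order),
    "0" = "C (µg/mL)", "1" = "ln C", "2" = "1/C (mL/µg)")
  d <- mutate(object$data, y = transform_response(.data$conc, object$order))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = if (object$order == 2) object$k else -object$k,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "time (h)", y = ylab,
      title = sprintf("%s fit: k = %.4g, R² = %.4f",
                      order_label(object$order), object$k, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname select_model
#' @export
autoplot.kinetic_screen <- function(object, ...) {
  d <- purrr::map_dfr(object$fits, function(f) {
    mutate(f$data,
           y = transform_response(.data$conc, f$order),
           panel = sprintf("%s (R² = %.4f)", order_label(f$order), f$r_squared),
           intercept = f$intercept,
           slope = if (f$order == 2) f$k else -f$k)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = dplyr::distinct(d, .data$panel, .data$intercept, .data$slope),
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope),
      colour = "steelblue"
    ) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "transformed concentration",
                  title = sprintf("Substitution method: %s selected",
                                  order_label(object$best_order))) +
    ggplot2::theme_minimal()
}

#' @rdname fit_calibration
#' @export
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc, y = .data$area)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "concentration (µg/mL)", y = "peak area",
      title = sprintf("area = %.5g conc + %.5g (r = %.4f)",
                      object$slope, object$intercept, object$r)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a chromatogram trace
#'
#' @param trace Tibble with `time` and `signal`.
#' @param windows Optional list of length-2 windows to shade.
#' @return A ggplot.
#' @export
plot_chromatogram <- function(trace, windows = NULL) {
  p <- ggplot2::ggplot(as_tibble(trace),
                       ggplot2::aes(x = .data$time, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "signal (AU)") +
    ggplot2::theme_minimal()
  if (!is.null(windows)) {
    if (!is.list(windows)) windows <- list(windows)
    shade <- purrr::map_dfr(windows, ~ tibble(xmin = .x[1], xmax = .x[2]))
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue"
    )
  }
  p
}
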
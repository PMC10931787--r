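#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted scale calibration
#'
#' Observed values against computed ideal-scale values with the fitted
#' affine calibration line.
#'
#' @param object A `thio_calibration` from [fit_linear_calibration()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.thio_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ideal,
                                            y = .data$observed)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$coefficients$slope,
                         intercept = object$coefficients$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "computed log10(k/kH), ideal scale",
      y = "observed log10(k/k2T), methanol scale",
      title = sprintf("Affine calibration: slope %.3f, intercept %.3f, r2 %.3f",
                      object$coefficients$slope,
                      object$coefficients$intercept, object$r2)
    )
}

#' Plot the baseline electronegativity correlation
#'
#' @param object A `thio_baseline` from [fit_baseline_chiM()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.thio_baseline <- function(object, ...) {
  d <- dplyr::mutate(object$data, log_chi = log10(.data$chi_M))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_chi,
                                  y = .data[[object$response]])) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "log10(chi_M / eV)", y = "log10 relative rate",
                  title = sprintf("One-descriptor baseline, r2 = %.3f",
                                  object$r2))
}

#' Plot the evolutionary fitness history
#'
#' Best-so-far raw R-squared (full data) per generation; non-decreasing by
#' construction under elitism.
#'
#' @param object A `gp_fit` from [gp_evolve()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.gp_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$generation, y = .data$best_raw_r2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "best-so-far raw R2",
                  title = "Symbolic-regression fitness history")
}

#' Plot predicted reactivity with classification thresholds
#'
#' Ideal-scale predictions per species, coloured by efficiency/safety
#' classification, with the decision threshold drawn.
#'
#' @param data Prediction tibble from [predict_reactivity()].
#' @param threshold_ideal Threshold line position. Default -3.
#' @return A ggplot.
#' @export
plot_reactivity <- function(data, threshold_ideal = -3) {
  stopifnot(all(c("species_id", "log_krel_ideal") %in% names(data)))
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = stats::reorder(.data$species_id, .data$log_krel_ideal),
                 y = .data$log_krel_ideal)
  )
  if ("classification" %in% names(data)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$classification))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p +
    ggplot2::geom_hline(yintercept = threshold_ideal, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "predicted log10(k/kH), ideal scale")
}
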
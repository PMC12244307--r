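#' Overlay the growth curves of several fits
#'
#' The standard cross-method comparison figure: expected length at age for
#' each fitted model, all curves forced through the origin (`t0 = 0`).
#'
#' @param fits A `compare_report`, or a (possibly named) list of
#'   `growth_fit` objects.
#' @param age_grid Ages (years) to evaluate at.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(fits, age_grid = seq(0, 10, by = 0.1)) {
  if (inherits(fits, "compare_report")) fits <- fits$fits
  if (inherits(fits, "growth_fit")) fits <- list(fits)
  curves <- purrr::map_dfr(fits, fitted_growth_curve,
                           age_grid = age_grid, zero_t0 = TRUE)
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$age, .data$length, colour = .data$label)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Age (years)", y = "Total length (mm)",
                  colour = "Model") +
    ggplot2::theme_minimal()
}

#' @rdname plot_growth_curves
#' @param object A `compare_report`.
#' @param ... Passed to [plot_growth_curves()].
#' @method autoplot compare_report
#' @export
autoplot.compare_report <- function(object, ...) {
  plot_growth_curves(object, ...)
}

#' Plot a length-frequency matrix
#'
#' Heat-map of counts (or restructured scores) over sampling date and length
#' bin; the visual on which cohort progressions are judged.
#'
#' @param object An `lfq_matrix` or `restructured_lfq`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lfq_matrix
#' @export
autoplot.lfq_matrix <- function(object, ...) {
  vals <- if (inherits(object, "restructured_lfq")) object$scores else object$counts
  # rows follow the column-major layout of the bins x dates matrix
  long <- tidyr::expand_grid(date = object$dates, bin = object$bin_mids)
  long$value <- as.vector(vals)
  ggplot2::ggplot(long, ggplot2::aes(.data$date, .data$bin,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "Sampling date", y = "Length bin midpoint (mm)",
                  fill = if (inherits(object, "restructured_lfq")) "Score" else "Count") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lfq_matrix
#' @method autoplot restructured_lfq
#' @export
autoplot.restructured_lfq <- autoplot.lfq_matrix

#' Simple length histogram / density export per sampling date
#'
#' Plumbing for a quick look at raw length-frequency samples.
#'
#' @param samples Data frame with `date` and `length` columns.
#' @param binwidth Histogram bin width, mm.
#' @return A ggplot object (faceted histograms by date).
#' @export
plot_length_histograms <- function(samples, binwidth = 10) {
  ggplot2::ggplot(samples, ggplot2::aes(.data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = NA) +
    ggplot2::facet_wrap(~date) +
    ggplot2::labs(x = "Total length (mm)", y = "Count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
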
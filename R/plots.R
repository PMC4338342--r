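#' Plot one hourly layer of a concentration field
#'
#' @param object A [conc_field()].
#' @param hour Hour of day, 0-23.
#' @param ... Unused.
#' @return A ggplot raster of the layer with cell-center coordinates in km.
#' @export
autoplot.conc_field <- function(object, hour = 7, ...) {
  g <- object$grid
  d <- tidyr::expand_grid(j = seq_len(g$ny) - 1L, i = seq_len(g$nx) - 1L)
  d$x <- (g$x0 + (d$i + 0.5) * g$cell_size_m) / 1000
  d$y <- (g$y0 + (d$j + 0.5) * g$cell_size_m) / 1000
  d$conc <- object$values[cbind(d$i + 1L, d$j + 1L, hour + 1L)]
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$conc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "NOx\n(µg/m³)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  title = sprintf("Hour %02d:00", hour))
}

#' Cumulative exposure distributions by group
#'
#' Empirical cumulative distributions of a per-person-day quantity for each
#' level of a grouping column, the standard way group exposure disparities
#' are displayed.
#'
#' @param records An [exposure_records()] tibble.
#' @param value Column to plot (tidy-eval), e.g. `c_activity` or
#'   `error_pct`.
#' @param by Grouping column (tidy-eval).
#' @return A ggplot.
#' @export
plot_exposure_cdf <- function(records, value, by) {
  ggplot2::ggplot(records,
                  ggplot2::aes({{ value }}, colour = factor({{ by }}))) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(y = "Cumulative fraction of person-days",
                  colour = rlang::as_name(rlang::enquo(by)))
}

#' Coefficient plot of a stepwise exposure model
#'
#' @param object A `stepwise_ols` fit.
#' @param ... Unused.
#' @return A ggplot of retained coefficients with 95% confidence bars.
#' @export
autoplot.stepwise_ols <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate,
                                   stats::reorder(.data$term,
                                                  .data$estimate))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Coefficient (µg/m³)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
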
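#' Plot seasonal food-group consumption
#'
#' Bar chart of the percentage of women consuming each food group, by
#' season (the seasonal consumption profile of the cohort).
#'
#' @param recalls Recall table (see [wdds10()]).
#' @return A ggplot object.
#' @export
plot_seasonal_consumers <- function(recalls) {
  seasonal_consumers(recalls) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$group, y = .data$pct_consumers,
                                 fill = .data$season)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Women consuming (%)", fill = "Season") +
    ggplot2::theme_minimal()
}

#' Plot dietary diversity by farm orientation
#'
#' Box plot of women's annual WDDS-10 by the market orientation of their
#' farm (self-consumption / market-oriented / mixed at the 80% value
#' threshold).
#'
#' @param dataset An `agridiet_survey`.
#' @return A ggplot object.
#' @export
plot_wdds_by_orientation <- function(dataset) {
  classify_orientation(dataset$production) |>
    dplyr::inner_join(dplyr::select(dataset$farms, "farm_id", "household_id"),
                      by = "farm_id") |>
    dplyr::inner_join(dplyr::select(dataset$women, "woman_id", "household_id"),
                      by = "household_id") |>
    dplyr::inner_join(annual_wdds(dataset$recalls), by = "woman_id") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$orientation,
                                 y = .data$annual_wdds)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Annual WDDS-10") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a LIML fit
#'
#' Point-and-interval plot of the coefficient estimates with approximate
#' 95% robust confidence intervals.
#'
#' @param object An `agridiet_liml` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot agridiet_liml
#' @export
autoplot.agridiet_liml <- function(object, ...) {
  tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$estimate,
                                 y = stats::reorder(.data$term,
                                                    .data$estimate))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Estimate (95% robust CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
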
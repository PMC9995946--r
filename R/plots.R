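# ggplot2 views of the main result types.

#' Plot score-over-age trendlines per cohort
#'
#' Scatter of an outcome against age, coloured by cohort, with linear
#' trendlines and 95% confidence bands.
#'
#' @param data Subject-level tibble.
#' @param outcome Numeric column to plot (a test score or e.g. `GM_TIV`).
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_trends <- function(data, outcome, alpha = 0.3) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$age, y = .data[[outcome]],
                                     colour = .data$cohort,
                                     fill = .data$cohort)) +
    ggplot2::geom_point(alpha = alpha, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, level = 0.95) +
    ggplot2::labs(x = "Age (years)", y = outcome, colour = "Cohort",
                  fill = "Cohort") +
    ggplot2::theme_minimal()
}

#' @method autoplot sfa_confusion
#' @export
autoplot.sfa_confusion <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n), .by = "true")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$assigned, y = .data$true,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n(%.1f%%)", .data$n, .data$pct))) +
    ggplot2::scale_y_discrete(limits = rev(cohort_levels())) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Assigned cohort", y = "True cohort",
                  fill = "% of row") +
    ggplot2::theme_minimal()
}

#' @method autoplot sfa_ranking
#' @export
autoplot.sfa_ranking <- function(object, top_n = 15, ...) {
  df <- utils::head(tibble::as_tibble(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Mean normalised impurity importance", y = NULL,
      title = sprintf("%s ~ morphometry in %s", attr(object, "test"),
                      attr(object, "cohort"))) +
    ggplot2::theme_minimal()
}
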
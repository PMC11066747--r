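#' Plot a cosinor fit over its data
#'
#' Observed hourly values as points with the fitted multi-component curve
#' overlaid.
#'
#' @param object A `rhythm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rhythm_fit
#' @export
autoplot.rhythm_fit <- function(object, ...) {
  s <- object$series
  grid <- seq(min(s$hour), max(s$hour), by = 0.1)
  curve <- tibble::tibble(hour = grid, value = eval_curve(object, grid))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$hour, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = curve, colour = "#2166AC", linewidth = 0.8) +
    ggplot2::labs(
      x = "hour from study midnight", y = "signal",
      title = sprintf("Cosinor fit: MESOR %.2f, IPR %.2f",
                      object$mesor, object$ipr)
    ) +
    ggplot2::theme_minimal()
}

#' Heat map of aggregate correlation or significance scores
#'
#' Mirrors the week-by-key score matrices of the aggregation stage: tiles
#' are keys (features or rhythm parameters) by scope (week or overall);
#' blank tiles are aggregates where no cell was individually significant.
#'
#' @param scores Aggregate-score tibble (weekly, overall, or both bound
#'   together).
#' @param value `"C"` (aggregate correlation, diverging scale) or `"S"`
#'   (significance score, sequential scale).
#' @return A ggplot.
#' @export
plot_score_heatmap <- function(scores, value = c("C", "S")) {
  value <- match.arg(value)
  col <- if (value == "C") "C_agg" else "S_score"
  p <- ggplot2::ggplot(
    scores,
    ggplot2::aes(x = .data$scope, y = .data$key, fill = .data[[col]])
  ) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$axis), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::theme_minimal()
  if (value == "C") {
    p + ggplot2::scale_fill_gradient2(low = "#B2182B", mid = "white",
                                      high = "#2166AC", midpoint = 0,
                                      na.value = "grey95")
  } else {
    p + ggplot2::scale_fill_viridis_c(na.value = "grey95")
  }
}
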
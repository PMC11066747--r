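#' Min-max normalization
#'
#' Rescales a vector affinely onto `[0, 1]`: `(x - min) / (max - min)`.
#' Because Pearson correlation is invariant under affine maps with positive
#' slope, this step cannot change any correlation or its significance; it
#' is retained so the correlation stage operates on commensurate scales.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return The rescaled vector.
#' @examples
#' minmax_normalize(c(1, 2, 3)) # 0 0.5 1
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2) {
    abort("Need at least 2 values.", class = "rhythmlink_error_degenerate_scale")
  }
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    abort("Cannot min-max normalize a constant vector.",
      class = "rhythmlink_error_degenerate_scale")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Pearson correlation with two-tailed significance for one cell
#'
#' Pairs the two vectors by position, drops pairs with a missing side,
#' and computes the sample Pearson r with its two-tailed p value from
#' `t = r * sqrt((n-2) / (1-r^2))` on `n-2` df (`|r| = 1` gives `p = 0`).
#'
#' @param param_values Per-participant rhythm-parameter values.
#' @param productivity_values Per-participant weekly mean scores, same
#'   order.
#' @return A list with `r`, `p`, `n`.
#' @export
correlation_cell <- function(param_values, productivity_values) {
  stopifnot(length(param_values) == length(productivity_values))
  ok <- is.finite(param_values) & is.finite(productivity_values)
  x <- param_values[ok]
  y <- productivity_values[ok]
  n <- length(x)
  if (n < 3) {
    abort("Fewer than 3 complete pairs.",
      class = "rhythmlink_error_insufficient_pairs")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance on one side of the correlation.",
      class = "rhythmlink_error_degenerate_scale")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Per-cell correlations between rhythm parameters and productivity
#'
#' Step 1 of the aggregation cascade: for every combination of behavioral
#' feature, rhythm parameter and survey week, min-max normalizes the
#' parameter values and the weekly mean scores across participants and
#' computes the Pearson correlation with its two-tailed p value. Cells
#' whose complete-pair count is not strictly greater than `min_n` are
#' excluded, as are degenerate (constant-side) cells; both are logged.
#'
#' @param rhythms Wide rhythm-parameter tibble from [fit_windows()] (one
#'   row per participant-feature-week, parameter columns as in
#'   [rhythm_fit_row()]).
#' @param weekly_scores Tibble from [weekly_mean_scores()] /
#'   [label_weeks()] with `participant_id`, `week`, `mean_score`.
#' @param min_n Observation-count filter: keep cells with `n > min_n`
#'   (default 28).
#' @return A list with `cells` (tibble: `feature`, `parameter`, `week`,
#'   `r`, `p`, `n`) and `log` (excluded cells with reasons).
#' @export
correlation_table <- function(rhythms, weekly_scores, min_n = 28L) {
  id_cols <- c("participant_id", "feature", "week", "n_obs")
  empty_cells <- tibble::tibble(feature = character(),
                                parameter = character(), week = integer(),
                                r = double(), p = double(), n = integer())
  if (nrow(rhythms) == 0) {
    warn("No rhythm fits supplied; empty correlation table.")
    return(list(cells = empty_cells, log = tibble::tibble()))
  }
  long <- rhythms |>
    tidyr::pivot_longer(-dplyr::any_of(id_cols), names_to = "parameter",
                        values_to = "value") |>
    dplyr::inner_join(
      dplyr::select(weekly_scores, "participant_id", "week", "mean_score"),
      by = c("participant_id", "week")
    )
  if (nrow(long) == 0) {
    warn("No joinable rhythm/productivity rows; empty correlation table.")
    return(list(cells = empty_cells, log = tibble::tibble()))
  }
  res <- long |>
    dplyr::group_by(.data$feature, .data$parameter, .data$week) |>
    dplyr::group_split() |>
    purrr::map(function(g) {
      key <- tibble::tibble(feature = g$feature[1], parameter = g$parameter[1],
                            week = g$week[1])
      ok <- is.finite(g$value) & is.finite(g$mean_score)
      n <- sum(ok)
      if (n <= min_n) {
        return(list(cell = NULL,
                    log = dplyr::mutate(key, n = n, reason = "n_below_filter")))
      }
      x <- g$value[ok]
      y <- g$mean_score[ok]
      if (sd(x) == 0 || sd(y) == 0) {
        return(list(cell = NULL,
                    log = dplyr::mutate(key, n = n, reason = "degenerate_scale")))
      }
      cc <- correlation_cell(minmax_normalize(x), minmax_normalize(y))
      list(cell = dplyr::mutate(key, r = cc$r, p = cc$p, n = cc$n), log = NULL)
    })
  list(
    cells = purrr::list_rbind(purrr::compact(purrr::map(res, "cell"))),
    log = purrr::list_rbind(purrr::compact(purrr::map(res, "log")))
  )
}
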
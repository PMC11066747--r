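#' Combine p values with Fisher's method
#'
#' `X = -2 * sum(log(p_i))` is referred to a chi-square distribution with
#' `2k` degrees of freedom; the combined p value is its upper-tail
#' probability. A single p value combines to itself. Exact zeros are
#' clamped to the smallest positive double with a warning, since
#' `log(0)` would be degenerate.
#'
#' @param p_values Numeric vector of p values in `(0, 1]`.
#' @return A list with `fisher_stat` and `combined_p`.
#' @examples
#' fisher_combine(0.5)$combined_p        # 0.5
#' fisher_combine(c(1, 1))$combined_p    # 1
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0) {
    abort("No p values to combine.", class = "rhythmlink_error_no_input")
  }
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("p values must lie in [0, 1].", class = "rhythmlink_error_no_input")
  }
  if (any(p_values == 0)) {
    warn("p values of 0 clamped to the smallest positive double.")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  x <- -2 * sum(log(p_values))
  list(fisher_stat = x,
       combined_p = pchisq(x, df = 2 * length(p_values), lower.tail = FALSE))
}

new_aggregate_score <- function(axis, key, scope, cells_r, cells_p, alpha,
                                s_cap) {
  fc <- fisher_combine(cells_p)
  sig <- cells_p < alpha
  tibble::tibble(
    axis = axis, key = key, scope = as.character(scope),
    C_agg = if (any(sig)) mean(cells_r[sig]) else NA_real_,
    fisher_stat = fc$fisher_stat,
    combined_p = fc$combined_p,
    S_score = min(-log10(fc$combined_p), s_cap),
    n_cells = length(cells_p),
    n_significant = sum(sig)
  )
}

#' Aggregate correlation cells along one axis for one week
#'
#' Step 2 of the cascade: all cells sharing one key (a feature, across
#' rhythm parameters; or a rhythm parameter, across features) and one week
#' are combined. The combined p value is Fisher's method over all cell
#' p values; the aggregate correlation `C` is the mean of the r values of
#' the individually significant cells (`p < alpha`), undefined — rendered
#' blank — when none is significant; the significance score `S` is
#' `-log10(combined_p)`, capped.
#'
#' @param cells Cell tibble rows sharing one axis key and week (columns
#'   `r`, `p` at minimum).
#' @param alpha Cell-level significance threshold (default 0.05).
#' @param s_cap Cap on the significance score (default 16).
#' @param axis,key,scope Identifiers carried into the result.
#' @return A one-row aggregate-score tibble: `axis`, `key`, `scope`,
#'   `C_agg`, `fisher_stat`, `combined_p`, `S_score`, `n_cells`,
#'   `n_significant`.
#' @export
aggregate_cells <- function(cells, alpha = 0.05, s_cap = 16,
                            axis = "feature", key = cells$feature[1],
                            scope = cells$week[1]) {
  if (nrow(cells) == 0) {
    abort("No cells to aggregate.", class = "rhythmlink_error_no_input")
  }
  new_aggregate_score(axis, key, scope, cells$r, cells$p, alpha, s_cap)
}

#' Combine weekly aggregate scores into an overall score
#'
#' Step 3 of the cascade (hierarchical reading): the overall combined p
#' value is Fisher's method over the weekly combined p values, and the
#' overall `C` is the mean of the defined weekly `C` values (weeks where
#' nothing was significant are skipped; if none is defined the overall `C`
#' is undefined while `S` is still computed).
#'
#' @param weekly Aggregate-score tibble rows for one key across weeks.
#' @param s_cap Cap on the significance score (default 16).
#' @return A one-row aggregate-score tibble with scope `"overall"`.
#' @export
combine_weeks <- function(weekly, s_cap = 16) {
  if (nrow(weekly) == 0) {
    abort("No weekly scores to combine.", class = "rhythmlink_error_no_input")
  }
  fc <- fisher_combine(weekly$combined_p)
  defined <- !is.na(weekly$C_agg)
  tibble::tibble(
    axis = weekly$axis[1], key = weekly$key[1], scope = "overall",
    C_agg = if (any(defined)) mean(weekly$C_agg[defined]) else NA_real_,
    fisher_stat = fc$fisher_stat,
    combined_p = fc$combined_p,
    S_score = min(-log10(fc$combined_p), s_cap),
    n_cells = sum(weekly$n_cells),
    n_significant = sum(weekly$n_significant)
  )
}

#' Full aggregation cascade over a correlation-cell table
#'
#' Runs steps 2-4 for both axes: per-feature and per-parameter weekly
#' aggregates, then cross-week combination into one overall score per key.
#' The default cross-week rule is hierarchical (Fisher over the weekly
#' combined p values); `cross_week = "pooled"` instead pools all cell-level
#' p values of a key across weeks into a single Fisher combination (the
#' overall `C` is then the mean of all individually significant cell r's).
#'
#' @param cells Cell tibble from [correlation_table()].
#' @param alpha Cell-level significance threshold (default 0.05).
#' @param s_cap Significance-score cap (default 16).
#' @param cross_week `"hierarchical"` (default) or `"pooled"`.
#' @return A list of tibbles: `weekly` (both axes, one row per key-week)
#'   and `overall` (one row per key).
#' @export
aggregate_scores <- function(cells, alpha = 0.05, s_cap = 16,
                             cross_week = c("hierarchical", "pooled")) {
  cross_week <- match.arg(cross_week)
  if (nrow(cells) == 0) {
    abort("Empty cell table.", class = "rhythmlink_error_no_input")
  }
  one_axis <- function(axis_col, axis_name) {
    weekly <- cells |>
      dplyr::group_by(key = .data[[axis_col]], week = .data$week) |>
      dplyr::group_split() |>
      purrr::map(function(g) {
        aggregate_cells(g, alpha, s_cap, axis = axis_name, key = g$key[1],
                        scope = g$week[1])
      }) |>
      purrr::list_rbind()
    overall <- if (cross_week == "hierarchical") {
      weekly |>
        dplyr::group_by(.data$key) |>
        dplyr::group_split() |>
        purrr::map(combine_weeks, s_cap = s_cap) |>
        purrr::list_rbind()
    } else {
      cells |>
        dplyr::group_by(key = .data[[axis_col]]) |>
        dplyr::group_split() |>
        purrr::map(function(g) {
          aggregate_cells(g, alpha, s_cap, axis = axis_name, key = g$key[1],
                          scope = "overall")
        }) |>
        purrr::list_rbind()
    }
    list(weekly = weekly, overall = overall)
  }
  fe <- one_axis("feature", "feature")
  pa <- one_axis("parameter", "parameter")
  list(weekly = dplyr::bind_rows(fe$weekly, pa$weekly),
       overall = dplyr::bind_rows(fe$overall, pa$overall))
}

#' Ranked report of aggregate scores
#'
#' For each axis, the top keys by absolute aggregate correlation
#' (undefined values last) and by significance score. Ties are broken
#' alphabetically by key, so the report is deterministic.
#'
#' @param scores Aggregate-score tibble (e.g. the `overall` element of
#'   [aggregate_scores()]).
#' @param top_k Rows to keep per ranking (default 10; clamped to what is
#'   available).
#' @return A list of tibbles per axis: `by_correlation`, `by_significance`.
#' @export
rank_report <- function(scores, top_k = 10L) {
  rank_one <- function(df, ord) head(df[ord, ], min(top_k, nrow(df)))
  purrr::map(split(scores, scores$axis), function(df) {
    list(
      by_correlation = rank_one(
        df, order(-abs(df$C_agg), df$key, na.last = TRUE)),
      by_significance = rank_one(df, order(-df$S_score, df$key))
    )
  })
}
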
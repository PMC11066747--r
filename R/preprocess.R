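#' Hourly statistical features from timestamped events
#'
#' Bins raw timestamped observations of one feature into clock hours and
#' emits five statistical series per hour: minimum, maximum, mean, sample
#' SD and event count. Hours inside the span with no events are flagged
#' missing in every series; the SD is additionally missing for hours with a
#' single event (undefined sample SD).
#'
#' @param events Data frame with numeric columns `timestamp` (hours from the
#'   study reference midnight, may be fractional) and `value`.
#' @param feature Base feature name; output series are named
#'   `<feature>_min`, `_max`, `_mean`, `_sd`, `_count`.
#' @param span Optional integer `c(first_hour, last_hour)` to cover; defaults
#'   to the hours spanned by the events.
#' @return A tibble in the hourly-series schema
#'   (`feature`, `hour`, `value`, `missing`), five series stacked.
#' @export
hourly_statistics <- function(events, feature = "feature", span = NULL) {
  if (!is.data.frame(events) || !all(c("timestamp", "value") %in% names(events))) {
    abort("`events` needs columns `timestamp` and `value`.",
      class = "rhythmlink_error_parse")
  }
  if (!is.numeric(events$value)) {
    num <- suppressWarnings(as.numeric(events$value))
    bad <- which(is.na(num) & !is.na(events$value))
    abort(paste0("Non-numeric value in `events` row ",
                 if (length(bad) > 0) bad[1] else 1L, "."),
      class = "rhythmlink_error_parse")
  }
  hours_of <- floor(events$timestamp)
  if (is.null(span)) span <- range(hours_of)
  all_hours <- seq.int(span[1], span[2])

  per_hour <- events |>
    dplyr::mutate(hour = as.integer(floor(.data$timestamp))) |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(
      min = min(.data$value), max = max(.data$value),
      mean = mean(.data$value),
      sd = if (dplyr::n() >= 2) stats::sd(.data$value) else NA_real_,
      count = as.numeric(dplyr::n()), .groups = "drop"
    )

  tidyr::expand_grid(stat = c("min", "max", "mean", "sd", "count"),
                     hour = as.integer(all_hours)) |>
    dplyr::left_join(
      tidyr::pivot_longer(per_hour, -"hour", names_to = "stat",
                          values_to = "value"),
      by = c("stat", "hour")
    ) |>
    dplyr::mutate(
      missing = is.na(.data$value),
      feature = paste0(.env$feature, "_", .data$stat)
    ) |>
    dplyr::select("feature", "hour", "value", "missing") |>
    dplyr::arrange(.data$feature, .data$hour)
}

#' Profile the missingness of one hourly series
#'
#' Reports the missing fraction and the lengths of maximal runs of
#' consecutive missing hours; the block-length SD is missing when fewer
#' than two blocks exist.
#'
#' @param series An hourly series tibble (`hour`, `value`, `missing`).
#' @return A list with `fraction_missing`, `block_lengths`, `mean_block`,
#'   `sd_block`.
#' @export
missingness_profile <- function(series) {
  check_hourly_series(series)
  r <- rle(series$missing)
  blocks <- r$lengths[r$values]
  list(
    fraction_missing = mean(series$missing),
    block_lengths = as.numeric(blocks),
    mean_block = if (length(blocks) > 0) mean(blocks) else NA_real_,
    sd_block = if (length(blocks) >= 2) stats::sd(blocks) else NA_real_
  )
}

#' Impute missing hours by linear interpolation
#'
#' Fills each interior missing run between observed anchors `v_a` at hour
#' `a` and `v_b` at hour `b` with points on the straight line
#' `v_t = v_a + (t - a) * (v_b - v_a) / (b - a)`; runs at the series
#' boundary, which have only one anchor, are filled with the nearest
#' observed value. Observed values are never altered.
#'
#' @param series An hourly series tibble with at least one observed value.
#' @return The series with every hour observed (`missing` all `FALSE`).
#' @export
impute_series <- function(series) {
  check_hourly_series(series)
  obs <- !series$missing
  if (!any(obs)) {
    abort("Cannot impute a fully missing series.",
      class = "rhythmlink_error_cannot_impute")
  }
  if (all(obs)) return(series)
  out <- series
  if (sum(obs) == 1) {
    out$value <- series$value[obs]
  } else {
    # interior: linear between nearest anchors; edges: nearest value (rule 2)
    out$value <- approx(x = series$hour[obs], y = series$value[obs],
                        xout = series$hour, method = "linear", rule = 2)$y
    out$value[obs] <- series$value[obs]
  }
  out$missing <- FALSE
  out
}

#' Retain and impute streams below a missingness threshold
#'
#' Applies the discard rule per stream (participant x feature, and per
#' window if a `window` column is present): streams whose missing fraction
#' is strictly below `max_missing` are imputed and retained; the rest are
#' discarded. Every decision is logged.
#'
#' @param streams Streams tibble (`participant_id`, `feature`, `hour`,
#'   `value`, `missing`, optionally `window`).
#' @param max_missing Discard threshold on the missing fraction; a stream is
#'   kept only if its fraction is `< max_missing`. Default 0.20.
#' @return A list with `retained` (imputed streams tibble) and `log`
#'   (tibble: participant_id, feature, [window,] fraction_missing, decision).
#' @export
select_streams <- function(streams, max_missing = 0.20) {
  if (max_missing <= 0 || max_missing > 1) {
    abort("`max_missing` must be in (0, 1].",
      class = "rhythmlink_error_invalid_config")
  }
  keys <- intersect(c("participant_id", "feature", "window"), names(streams))
  if (nrow(streams) == 0) {
    return(list(retained = streams,
                log = tibble::tibble(fraction_missing = double(),
                                     decision = character())))
  }
  pieces <- streams |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_split()
  decisions <- purrr::map(pieces, function(s) {
    frac <- mean(s$missing)
    keep <- frac < max_missing
    log_row <- dplyr::bind_cols(
      dplyr::distinct(s[, keys, drop = FALSE]),
      tibble::tibble(fraction_missing = frac,
                     decision = if (keep) "retained" else "discarded")
    )
    list(retained = if (keep) impute_series(s) else NULL, log = log_row)
  })
  list(
    retained = purrr::list_rbind(purrr::compact(purrr::map(decisions, "retained"))),
    log = purrr::list_rbind(purrr::map(decisions, "log"))
  )
}
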
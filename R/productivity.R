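#' Weekly mean productivity scores
#'
#' Averages the daily 0-4 self-reports over all available days of each
#' survey week (weekdays and weekends alike). Participants with no records
#' in a week simply contribute no row for it; `n_days` records how many
#' days the mean rests on.
#'
#' @param records Productivity tibble (`participant_id`, `day`, `week`,
#'   `score`).
#' @param weeks Optional week indices to restrict to.
#' @return A tibble: `participant_id`, `week`, `mean_score`, `n_days`.
#' @export
weekly_mean_scores <- function(records, weeks = NULL) {
  if (any(records$score < 0 | records$score > 4)) {
    abort("Scores must lie in 0..4.", class = "rhythmlink_error_invalid_score")
  }
  if (!is.null(weeks)) records <- dplyr::filter(records, .data$week %in% weeks)
  records |>
    dplyr::group_by(.data$participant_id, .data$week) |>
    dplyr::summarise(mean_score = mean(.data$score), n_days = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$participant_id, .data$week)
}

#' Label a weekly mean score as high or low productivity
#'
#' A week is highly productive iff its mean score is greater than or equal
#' to the threshold (default 2, the midpoint of the 0-4 scale).
#'
#' @param mean_score Numeric vector of weekly means in `[0, 4]`.
#' @param threshold Cutoff (default 2); `mean_score >= threshold` is high.
#' @return Character vector, `"high"` or `"low"`.
#' @examples
#' label_week(c(2, 1.99, 4)) # "high" "low" "high"
#' @export
label_week <- function(mean_score, threshold = 2) {
  if (any(mean_score < 0 | mean_score > 4 | !is.finite(mean_score))) {
    abort("`mean_score` must lie in [0, 4].",
      class = "rhythmlink_error_invalid_score")
  }
  ifelse(mean_score >= threshold, "high", "low")
}

#' Weekly productivity labels for a whole cohort
#'
#' @inheritParams weekly_mean_scores
#' @param threshold Passed to [label_week()].
#' @return A tibble: `participant_id`, `week`, `mean_score`, `n_days`,
#'   `label`.
#' @export
label_weeks <- function(records, weeks = NULL, threshold = 2) {
  weekly_mean_scores(records, weeks) |>
    dplyr::mutate(label = label_week(.data$mean_score, threshold))
}

#' Assign one participant to a productivity group
#'
#' A participant belongs to the high-productivity group iff at least
#' `min_high` of the survey weeks are labeled high (default 2 of 3). The
#' decision depends only on the multiset of labels, not their order.
#'
#' @param labels Character vector of week labels (`"high"`/`"low"`), one
#'   per survey week.
#' @param n_weeks_expected Number of survey weeks that must be labeled
#'   (default 3).
#' @param min_high Minimum count of high weeks for the high group.
#' @return `"high"` or `"low"`.
#' @examples
#' assign_participant_group(c("high", "high", "low")) # "high"
#' assign_participant_group(c("high", "low", "low"))  # "low"
#' @export
assign_participant_group <- function(labels, n_weeks_expected = 3L,
                                     min_high = 2L) {
  if (length(labels) != n_weeks_expected || anyNA(labels)) {
    abort("Need exactly one label per survey week.",
      class = "rhythmlink_error_incomplete_labels")
  }
  if (!all(labels %in% c("high", "low"))) {
    abort("Labels must be 'high' or 'low'.",
      class = "rhythmlink_error_incomplete_labels")
  }
  if (sum(labels == "high") >= min_high) "high" else "low"
}

#' Productivity groups for a whole cohort
#'
#' Participants lacking a label for any survey week are excluded and
#' logged rather than failing the cohort — incomplete survey response is
#' expected in field data.
#'
#' @param week_labels Output of [label_weeks()].
#' @param survey_weeks The survey weeks every participant must have.
#' @param min_high Minimum high weeks for the high group (default 2).
#' @return A list with `groups` (tibble: `participant_id`, `n_high_weeks`,
#'   `group`) and `excluded` (participants with incomplete labels).
#' @export
participant_groups <- function(week_labels, survey_weeks = c(1L, 6L, 15L),
                               min_high = 2L) {
  survey_weeks <- sort(unique(as.integer(survey_weeks)))
  by_p <- week_labels |>
    dplyr::filter(.data$week %in% survey_weeks) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_weeks = dplyr::n(),
                     n_high_weeks = sum(.data$label == "high"),
                     .groups = "drop")
  complete <- by_p$n_weeks == length(survey_weeks)
  groups <- by_p[complete, ] |>
    dplyr::mutate(group = ifelse(.data$n_high_weeks >= min_high,
                                 "high", "low")) |>
    dplyr::select("participant_id", "n_high_weeks", "group")
  list(groups = groups,
       excluded = by_p$participant_id[!complete])
}
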
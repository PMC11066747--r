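# Internal helpers shared across modules.

#' Derive a reproducible substream seed
#'
#' Expands one global seed into independent per-unit seeds by a counter-based
#' affine map modulo the largest 32-bit prime, so that adding units to a
#' simulation never perturbs the draws of existing units.
#'
#' @param seed Integer base seed.
#' @param counter Non-negative integer stream counter (0 = the base stream).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  # 2147483647 = 2^31 - 1 (prime); 1000003 is coprime to it
  as.integer((as.double(seed) %% 2147483647 + 1000003 * as.double(counter)) %% 2147483647)
}

# Validate a single hourly series tibble (one participant x feature).
check_hourly_series <- function(series, require_complete = FALSE) {
  needed <- c("hour", "value", "missing")
  if (!is.data.frame(series) || !all(needed %in% names(series))) {
    abort("`series` must be a data frame with columns hour, value, missing.",
      class = "rhythmlink_error_bad_series")
  }
  if (nrow(series) == 0) {
    abort("`series` is empty.", class = "rhythmlink_error_bad_series")
  }
  if (is.unsorted(series$hour, strictly = TRUE)) {
    abort("`series$hour` must be strictly increasing.",
      class = "rhythmlink_error_bad_series")
  }
  if (any(!series$missing & !is.finite(series$value))) {
    abort("Non-missing values must be finite.",
      class = "rhythmlink_error_bad_series")
  }
  if (require_complete && any(series$missing)) {
    abort("`series` still contains missing hours; impute first.",
      class = "rhythmlink_error_missing_values")
  }
  invisible(series)
}

# Least common multiple of a set of positive numbers that are integral
# when expressed in hours (sufficient for the 8/12/24 design).
lcm_hours <- function(x) {
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  Reduce(function(a, b) a * b / gcd2(a, b), x)
}

# Map week index (1-based) to the half-open hour range [from, to).
week_hour_range <- function(week, hours_per_week = 168L) {
  c(from = (week - 1L) * hours_per_week, to = week * hours_per_week)
}
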
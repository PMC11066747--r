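#' Define a participant rhythm profile
#'
#' A rhythm profile parameterizes the generative cosinor form for one
#' participant and feature: a midline (MESOR), one amplitude/acrophase pair
#' per periodic component, additive Gaussian noise, and day-level jitter of
#' phase and amplitude that models between-day rhythm instability.
#'
#' @param mesor Midline of the rhythm, in signal units.
#' @param amplitudes Named numeric vector of non-negative component
#'   amplitudes; names are period lengths in hours (e.g. `c("24" = 2)`).
#' @param acrophases Named numeric vector of acrophases, hours from midnight
#'   to the component peak, each in `[0, period)`; names as in `amplitudes`.
#' @param noise_sd Standard deviation of additive hourly Gaussian noise.
#' @param phase_jitter_sd Day-to-day standard deviation of the acrophase, in
#'   hours. Larger values mean a less stable rhythm.
#' @param amp_jitter_sd Day-to-day standard deviation of the multiplicative
#'   amplitude perturbation, as a fraction of the base amplitude.
#' @return An object of class `rhythm_profile`.
#' @examples
#' rhythm_profile(10, c("24" = 2), c("24" = 14))
#' @export
rhythm_profile <- function(mesor, amplitudes, acrophases, noise_sd = 0,
                           phase_jitter_sd = 0, amp_jitter_sd = 0) {
  if (is.null(names(amplitudes)) || is.null(names(acrophases)) ||
      !setequal(names(amplitudes), names(acrophases))) {
    abort("`amplitudes` and `acrophases` must be named by the same periods.",
      class = "rhythmlink_error_bad_profile")
  }
  acrophases <- acrophases[names(amplitudes)]
  periods <- as.numeric(names(amplitudes))
  if (any(!is.finite(periods) | periods <= 0)) {
    abort("Periods must be positive numbers of hours.",
      class = "rhythmlink_error_bad_profile")
  }
  if (any(amplitudes < 0)) {
    abort("Amplitudes must be non-negative.",
      class = "rhythmlink_error_bad_profile")
  }
  if (any(acrophases < 0 | acrophases >= periods)) {
    abort("Each acrophase must lie in [0, period).",
      class = "rhythmlink_error_bad_profile")
  }
  if (noise_sd < 0 || phase_jitter_sd < 0 || amp_jitter_sd < 0) {
    abort("Noise and jitter SDs must be non-negative.",
      class = "rhythmlink_error_bad_profile")
  }
  structure(
    list(mesor = mesor, amplitudes = amplitudes, acrophases = acrophases,
         periods = periods, noise_sd = noise_sd,
         phase_jitter_sd = phase_jitter_sd, amp_jitter_sd = amp_jitter_sd),
    class = "rhythm_profile"
  )
}

#' Simulate one hourly feature stream
#'
#' Generates the value at hour `t` as
#' `mesor + sum_c a_c(d) * cos(2*pi*(t - phi_c(d)) / T_c) + eps_t`,
#' where `d` is the day index, the per-day acrophase `phi_c(d)` and amplitude
#' `a_c(d)` are jittered around their profile values by the profile's SDs,
#' and `eps_t` is iid Gaussian noise. The draw order is fixed (per-day jitter
#' first, then hourly noise), so equal seeds give bitwise-equal streams.
#'
#' @param profile A [rhythm_profile()].
#' @param n_hours Number of hourly samples (>= 24); hours run `0 .. n_hours-1`
#'   from local midnight of day 1.
#' @param seed Integer seed.
#' @return A tibble with columns `hour`, `value`, `missing` (all `FALSE`).
#' @examples
#' s <- simulate_feature_stream(rhythm_profile(10, c("24" = 2), c("24" = 14)), 48, seed = 1)
#' s$value[s$hour == 14] # peak: 12
#' @export
simulate_feature_stream <- function(profile, n_hours, seed) {
  stopifnot(inherits(profile, "rhythm_profile"))
  if (n_hours < 24) {
    abort("`n_hours` must be at least 24 (one full day).",
      class = "rhythmlink_error_invalid_length")
  }
  n_hours <- as.integer(n_hours)
  hours <- seq_len(n_hours) - 1L
  days <- hours %/% 24L
  n_days <- max(days) + 1L
  k <- length(profile$periods)

  withr::with_seed(derive_seed(seed, 0L), {
    # per-day jitter drawn first: k x n_days phase offsets, then amp factors
    phase_jit <- matrix(rnorm(k * n_days, 0, profile$phase_jitter_sd),
                        nrow = k)
    amp_fac <- matrix(pmax(0, 1 + rnorm(k * n_days, 0, profile$amp_jitter_sd)),
                      nrow = k)
    value <- rep(profile$mesor, n_hours)
    for (c_i in seq_len(k)) {
      t_c <- profile$periods[c_i]
      phi <- profile$acrophases[c_i] + phase_jit[c_i, days + 1L]
      a <- profile$amplitudes[c_i] * amp_fac[c_i, days + 1L]
      value <- value + a * cos(2 * pi * (hours - phi) / t_c)
    }
    if (profile$noise_sd > 0) {
      value <- value + rnorm(n_hours, 0, profile$noise_sd)
    }
    tibble::tibble(hour = hours, value = value, missing = FALSE)
  })
}

#' Inject block-structured missingness into an hourly series
#'
#' Marks hours missing in contiguous blocks whose lengths are geometric with
#' the requested mean, alternating with geometric observed gaps sized so that
#' the expected missing fraction matches `fraction`. Observed values are
#' never altered; missing hours get `NA` values and `missing = TRUE`.
#'
#' @param series An hourly series tibble (`hour`, `value`, `missing`).
#' @param fraction Target missing fraction in `[0, 1)`.
#' @param block_mean Target mean missing-block length in hours (>= 1).
#' @param seed Integer seed.
#' @return The series with a block-structured missing mask.
#' @export
inject_missing <- function(series, fraction, block_mean = 1.7, seed = 1L) {
  check_hourly_series(series)
  if (fraction < 0 || fraction >= 1) {
    abort("`fraction` must be in [0, 1).",
      class = "rhythmlink_error_invalid_fraction")
  }
  if (block_mean < 1) {
    abort("`block_mean` must be at least 1 hour.",
      class = "rhythmlink_error_invalid_fraction")
  }
  if (fraction == 0) return(series)
  n <- nrow(series)
  gap_mean <- block_mean * (1 - fraction) / fraction
  p_block <- 1 / block_mean
  p_gap <- 1 / max(gap_mean, 1)

  mask <- withr::with_seed(derive_seed(seed, 0L), {
    m <- logical(n)
    # alternate observed gap / missing block; start state chosen by the
    # stationary probability so short series are not biased toward observed
    pos <- 1L
    in_block <- rbinom(1L, 1L, fraction) == 1L
    while (pos <= n) {
      len <- 1L + rgeom(1L, if (in_block) p_block else p_gap)
      end <- min(n, pos + len - 1L)
      if (in_block) m[pos:end] <- TRUE
      pos <- end + 1L
      in_block <- !in_block
    }
    m
  })
  # bounds forced by construction: at least one missing hour when a positive
  # fraction was requested, and at least one observed hour always
  if (!any(mask)) {
    mask[seq_len(min(n - 1L, max(1L, as.integer(round(block_mean)))))] <- TRUE
  }
  if (all(mask)) mask[1L] <- FALSE
  out <- series
  out$missing <- mask
  out$value[mask] <- NA_real_
  out
}

#' Simulate daily productivity self-reports
#'
#' Each day's 0-4 score is generated as
#' `clamp(round(2 + coupling * stability + N(0, sigma_day)), 0, 4)`:
#' a Gaussian latent centred at the scale midpoint, shifted by the
#' participant's latent rhythm stability, then rounded and clamped to the
#' survey scale. Records are emitted only for the survey weeks.
#'
#' @param stability Latent rhythm-stability score (standardized to mean 0,
#'   SD 1 across the cohort by the caller).
#' @param survey_weeks Integer vector of week indices with surveys.
#' @param days_per_week Days reported per survey week (default 7).
#' @param coupling Slope linking stability to the expected daily score.
#' @param sigma_day Daily noise SD on the latent scale.
#' @param seed Integer seed.
#' @return A tibble with columns `day`, `week`, `score`.
#' @export
simulate_productivity <- function(stability, survey_weeks = c(1L, 6L, 15L),
                                  days_per_week = 7L, coupling = 0.8,
                                  sigma_day = 0.7, seed = 1L) {
  if (length(survey_weeks) == 0) {
    abort("`survey_weeks` must not be empty.",
      class = "rhythmlink_error_invalid_config")
  }
  stopifnot(is.finite(coupling), sigma_day >= 0, days_per_week >= 1)
  survey_weeks <- sort(unique(as.integer(survey_weeks)))
  n <- length(survey_weeks) * days_per_week
  withr::with_seed(derive_seed(seed, 0L), {
    latent <- 2 + coupling * stability + rnorm(n, 0, sigma_day)
    score <- pmin(4L, pmax(0L, as.integer(round(latent))))
    tibble::tibble(
      week = rep(survey_weeks, each = days_per_week),
      day = (rep(survey_weeks, each = days_per_week) - 1L) * 7L +
        rep(seq_len(days_per_week), times = length(survey_weeks)),
      score = score
    )[, c("day", "week", "score")]
  })
}

#' Default two-group stability profiles for the cohort generator
#'
#' Two equal-sized groups differing only in day-to-day phase jitter:
#' a high-stability group (0.5 h SD) and a low-stability group (3 h SD).
#' All other profile parameters are sampled uniformly from the same ranges,
#' so the planted productivity effect is carried by rhythm stability alone.
#'
#' @return A named list of group specifications; each holds uniform sampling
#'   ranges per profile field (a length-2 numeric `c(lo, hi)`).
#' @export
default_group_profiles <- function() {
  base <- list(
    mesor = c(8, 12),
    amp_24 = c(2, 4), amp_12 = c(0.5, 1.5), amp_8 = c(0.2, 0.8),
    acro_24 = c(10, 18), acro_12 = c(0, 12), acro_8 = c(0, 8),
    noise_sd = c(0.8, 1.2),
    amp_jitter_sd = c(0.05, 0.15)
  )
  list(
    high_stability = c(base, list(phase_jitter_sd = c(0.5, 0.5))),
    low_stability = c(base, list(phase_jitter_sd = c(3, 3)))
  )
}

#' Build a simulation configuration
#'
#' Bundles every knob of the synthetic cohort: size, study span, survey
#' weeks, features, group profiles, the stability-to-productivity coupling,
#' and the missingness process. Defaults mirror the study design the
#' pipeline targets: 16 weeks of continuous hourly data with productivity
#' surveys in weeks 1, 6 and 15.
#'
#' @param n_participants Cohort size (>= 1).
#' @param n_weeks Study length in weeks (168 hours each).
#' @param survey_weeks Weeks with productivity surveys (subset of
#'   `1..n_weeks`).
#' @param features Character vector of feature-stream names per participant.
#' @param group_profiles Named list of group specs, as
#'   [default_group_profiles()].
#' @param coupling Slope linking latent stability to expected daily score.
#' @param sigma_day Daily score noise SD.
#' @param missing_fraction Target missing fraction per stream, in `[0, 1)`.
#' @param missing_block_mean Mean missing-block length in hours.
#' @param seed Integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 100L, n_weeks = 16L,
                              survey_weeks = c(1L, 6L, 15L),
                              features = c("steps", "phone_use"),
                              group_profiles = default_group_profiles(),
                              coupling = 0.8, sigma_day = 0.7,
                              missing_fraction = 0.1,
                              missing_block_mean = 1.7, seed = 1L) {
  if (n_participants < 1) {
    abort("`n_participants` must be >= 1.",
      class = "rhythmlink_error_invalid_config")
  }
  survey_weeks <- sort(unique(as.integer(survey_weeks)))
  if (!all(survey_weeks >= 1 & survey_weeks <= n_weeks)) {
    abort("`survey_weeks` must lie within 1..n_weeks.",
      class = "rhythmlink_error_invalid_config")
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    abort("`missing_fraction` must be in [0, 1).",
      class = "rhythmlink_error_invalid_config")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_weeks = as.integer(n_weeks), survey_weeks = survey_weeks,
         features = features, group_profiles = group_profiles,
         coupling = coupling, sigma_day = sigma_day,
         missing_fraction = missing_fraction,
         missing_block_mean = missing_block_mean, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

sample_range <- function(range) {
  if (range[1] == range[2]) range[1] else stats::runif(1, range[1], range[2])
}

#' Simulate a full cohort
#'
#' Generates one hourly stream per participant and feature over the study
#' span, injects block missingness, and produces daily productivity scores
#' coupled to each participant's latent rhythm stability. Stability is the
#' standardized negative day-to-day phase jitter across the cohort, so
#' participants with steadier rhythms get higher expected scores when
#' `coupling > 0`. Ground-truth profiles are retained for parameter-recovery
#' tests. Per-participant seed substreams make the bundle reproducible and
#' insensitive to cohort growth.
#'
#' @param config A [simulation_config()].
#' @return A list of class `rhythm_cohort` with tibbles `streams`
#'   (`participant_id`, `feature`, `hour`, `value`, `missing`),
#'   `productivity` (`participant_id`, `day`, `week`, `score`), `profiles`
#'   (ground truth per participant), and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_participants
  groups <- names(config$group_profiles)
  # deterministic near-equal split across groups by participant index
  group_of <- groups[((seq_len(n) - 1L) %% length(groups)) + 1L]
  ids <- sprintf("P%03d", seq_len(n))
  n_hours <- config$n_weeks * 168L

  profiles <- purrr::map(seq_len(n), function(i) {
    spec <- config$group_profiles[[group_of[i]]]
    withr::with_seed(derive_seed(config$seed, i * 17L), {
      fields <- purrr::map_dbl(spec, sample_range)
      tibble::tibble(
        participant_id = ids[i], group = group_of[i],
        mesor = fields[["mesor"]],
        amp_8 = fields[["amp_8"]], amp_12 = fields[["amp_12"]],
        amp_24 = fields[["amp_24"]],
        acro_8 = fields[["acro_8"]] %% 8, acro_12 = fields[["acro_12"]] %% 12,
        acro_24 = fields[["acro_24"]] %% 24,
        noise_sd = fields[["noise_sd"]],
        phase_jitter_sd = fields[["phase_jitter_sd"]],
        amp_jitter_sd = fields[["amp_jitter_sd"]]
      )
    })
  }) |> purrr::list_rbind()

  jit <- profiles$phase_jitter_sd
  stability <- if (sd(jit) > 0) as.numeric(scale(-jit)) else rep(0, n)
  profiles$stability <- stability

  streams <- purrr::map(seq_len(n), function(i) {
    pr <- profiles[i, ]
    purrr::map(seq_along(config$features), function(f) {
      prof <- rhythm_profile(
        mesor = pr$mesor,
        amplitudes = c("8" = pr$amp_8, "12" = pr$amp_12, "24" = pr$amp_24),
        acrophases = c("8" = pr$acro_8, "12" = pr$acro_12, "24" = pr$acro_24),
        noise_sd = pr$noise_sd, phase_jitter_sd = pr$phase_jitter_sd,
        amp_jitter_sd = pr$amp_jitter_sd
      )
      s_seed <- derive_seed(config$seed, i * 1009L + f * 31L)
      s <- simulate_feature_stream(prof, n_hours, seed = s_seed)
      if (config$missing_fraction > 0) {
        s <- inject_missing(s, config$missing_fraction,
                            config$missing_block_mean,
                            seed = derive_seed(s_seed, 1L))
      }
      dplyr::mutate(s, participant_id = ids[i],
                    feature = config$features[f], .before = 1)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  productivity <- purrr::map(seq_len(n), function(i) {
    simulate_productivity(stability[i], config$survey_weeks,
                          days_per_week = 7L, coupling = config$coupling,
                          sigma_day = config$sigma_day,
                          seed = derive_seed(config$seed, i * 7919L)) |>
      dplyr::mutate(participant_id = ids[i], .before = 1)
  }) |> purrr::list_rbind()

  structure(
    list(streams = streams, productivity = productivity,
         profiles = profiles, config = config),
    class = "rhythm_cohort"
  )
}

#' Write a cohort bundle to disk
#'
#' Streams and productivity go to CSV; ground-truth profiles to a JSON
#' sidecar.
#'
#' @param cohort A `rhythm_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rhythm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    streams = file.path(dir, "streams.csv"),
    productivity = file.path(dir, "productivity.csv"),
    profiles = file.path(dir, "ground_truth.json")
  )
  streams_out <- dplyr::mutate(cohort$streams,
                               missing = as.integer(.data$missing))
  readr::write_csv(streams_out, paths[["streams"]])
  readr::write_csv(cohort$productivity, paths[["productivity"]])
  jsonlite::write_json(cohort$profiles, paths[["profiles"]],
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read hourly streams from the CSV schema
#'
#' @param path CSV with columns
#'   `participant_id, feature, hour, value, missing` (missing coded 0/1).
#' @return A streams tibble with a logical `missing` column.
#' @export
read_streams <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(missing = as.logical(.data$missing))
}
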
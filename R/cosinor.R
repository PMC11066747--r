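#' Build the linearized cosinor design matrix
#'
#' The multi-component cosinor model
#' `y_i = M + sum_c A_c * cos(2*pi*(t_i - phi_c)/T_c) + e_i`
#' is linear in `(M, beta_c, gamma_c)` after expanding each component into a
#' cosine and a sine regressor: `beta_c = A_c cos(2*pi*phi_c/T_c)`,
#' `gamma_c = A_c sin(2*pi*phi_c/T_c)`. The reference time 0 is local
#' midnight of the window start.
#'
#' @param times Numeric vector of sampling times in hours.
#' @param periods Component periods in hours (default `c(8, 12, 24)`).
#' @return An object of class `cosinor_design`: list with the model matrix
#'   `x` (columns `(Intercept)`, `cos_T`, `sin_T` per period), `times`,
#'   `periods`, and `fundamental_period` (LCM of the periods).
#' @examples
#' d <- build_design(0:23, periods = c(8, 12, 24))
#' dim(d$x)                 # 24 x 7
#' d$fundamental_period     # 24
#' @export
build_design <- function(times, periods = c(8, 12, 24)) {
  periods <- as.numeric(periods)
  if (any(periods <= 0) || anyDuplicated(periods) > 0) {
    abort("`periods` must be distinct positive hours.",
      class = "rhythmlink_error_bad_periods")
  }
  if (length(unique(times)) < 2 * length(periods) + 2) {
    abort("Need at least 2 * n_periods + 2 distinct times.",
      class = "rhythmlink_error_underdetermined")
  }
  cols <- purrr::map(periods, function(t_c) {
    m <- cbind(cos(2 * pi * times / t_c), sin(2 * pi * times / t_c))
    colnames(m) <- paste0(c("cos_", "sin_"), t_c)
    m
  })
  x <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  structure(
    list(x = x, times = times, periods = periods,
         fundamental_period = lcm_hours(periods)),
    class = "cosinor_design"
  )
}

#' Polar rhythm parameters from linear cosinor coefficients
#'
#' Maps the cosine/sine coefficient pair of one component to amplitude and
#' acrophase, with delta-method standard errors propagated through the
#' polar transform:
#' `A = sqrt(beta^2 + gamma^2)`, `phi = (T / 2*pi) * atan2(gamma, beta) mod T`
#' (hours from the reference time to the component peak). The acrophase SE
#' is reported in hours; it is undefined (NA) at zero amplitude, where the
#' phase is unidentified.
#'
#' @param beta,gamma Cosine and sine coefficients.
#' @param covariance Coefficient covariance block: either the 2x2
#'   `(beta, gamma)` block, or the 3x3 `(intercept, beta, gamma)` block, in
#'   which case the MESOR SE is also returned.
#' @param period Component period in hours.
#' @return A tibble with `amplitude`, `acrophase`, `amp_se`, `phi_se`,
#'   `mesor_se` (NA unless a 3x3 covariance was given).
#' @export
component_parameters <- function(beta, gamma, covariance, period) {
  covariance <- as.matrix(covariance)
  if (nrow(covariance) == 3) {
    mesor_se <- sqrt(covariance[1, 1])
    v <- covariance[2:3, 2:3]
  } else {
    mesor_se <- NA_real_
    v <- covariance
  }
  stopifnot(nrow(v) == 2, ncol(v) == 2)
  a <- sqrt(beta^2 + gamma^2)
  phi <- ((period / (2 * pi)) * atan2(gamma, beta)) %% period
  if (a > 0) {
    # gradients of the polar transform
    g_a <- c(beta, gamma) / a
    amp_se <- sqrt(drop(t(g_a) %*% v %*% g_a))
    g_phi <- c(-gamma, beta) / a^2           # d(atan2)/d(beta, gamma)
    phi_se <- (period / (2 * pi)) * sqrt(drop(t(g_phi) %*% v %*% g_phi))
  } else {
    amp_se <- sqrt((v[1, 1] + v[2, 2]) / 2)
    phi_se <- NA_real_
  }
  tibble::new_tibble(list(amplitude = a, acrophase = phi, amp_se = amp_se,
                          phi_se = phi_se, mesor_se = mesor_se), nrow = 1L)
}

# Internal OLS on a cosinor design via lm(); returns the lm fit plus the
# design, so downstream code shares one fitting path.
fit_design <- function(y, design) {
  x <- design$x
  df <- as.data.frame(x[, -1, drop = FALSE])
  df$y <- y
  fit <- lm(y ~ ., data = df)
  if (any(is.na(coef(fit)))) {
    abort("Cosinor design is rank deficient for these times.",
      class = "rhythmlink_error_singular_fit")
  }
  fit
}

#' Fit the multi-component cosinor model to one hourly series
#'
#' Ordinary least squares on the linearized design, followed by the polar
#' re-parameterization of each component ([component_parameters()]),
#' per-period percent rhythm and zero-amplitude tests
#' ([rhythm_tests()]), and grid extrema of the full fitted curve
#' ([curve_extrema()]). A constant series fits successfully with near-zero
#' amplitudes and non-significant tests.
#'
#' @param series An imputed hourly series tibble (`hour`, `value`,
#'   `missing` all `FALSE`); extra id columns (`participant_id`, `feature`,
#'   `week`) are carried through if present.
#' @param periods Component periods in hours (default `c(8, 12, 24)`).
#' @return An object of class `rhythm_fit`; see [tidy.rhythm_fit()] and
#'   [glance.rhythm_fit()] for tabular views and [rhythm_fit_row()] for the
#'   one-row wide form used in rhythm-parameter tables.
#' @examples
#' s <- simulate_feature_stream(rhythm_profile(10, c("24" = 2), c("24" = 14)), 72, seed = 1)
#' fit <- fit_cosinor(s, periods = 24)
#' tidy(fit)
#' @export
fit_cosinor <- function(series, periods = c(8, 12, 24)) {
  check_hourly_series(series, require_complete = TRUE)
  design <- build_design(series$hour, periods)
  fit <- fit_design(series$value, design)
  n <- nrow(series)
  p <- length(coef(fit))
  sigma2 <- sum(fit$residuals^2) / (n - p)
  # covariance from the QR factors directly; robust to zero-residual fits
  piv <- fit$qr$pivot
  unscaled <- matrix(0, p, p)
  unscaled[piv, piv] <- chol2inv(qr.R(fit$qr))
  cv <- sigma2 * unscaled

  comps <- purrr::map(seq_along(design$periods), function(i) {
    t_c <- design$periods[i]
    idx <- c(1L, 2L * i, 2L * i + 1L)
    cp <- component_parameters(coef(fit)[[2L * i]], coef(fit)[[2L * i + 1L]],
                               cv[idx, idx], t_c)
    tibble::new_tibble(
      c(list(period = t_c, beta = coef(fit)[[2L * i]],
             gamma = coef(fit)[[2L * i + 1L]]),
        as.list(cp)),
      nrow = 1L)
  }) |> purrr::list_rbind()

  tests <- rhythm_tests(series, periods)
  ord <- match(comps$period, tests$per_period$period)
  comps$pr <- tests$per_period$pr[ord]
  comps$p_value <- tests$per_period$p_value[ord]

  out <- structure(
    list(
      participant_id = series[["participant_id"]][1] %||% NA_character_,
      feature = series[["feature"]][1] %||% NA_character_,
      week = series[["week"]][1] %||% NA_integer_,
      n_obs = n,
      mesor = coef(fit)[[1L]], mesor_se = sqrt(cv[1L, 1L]),
      components = comps,
      ipr = tests$ipr, ip = tests$ip,
      residual_variance = sigma2,
      fundamental_period = design$fundamental_period,
      series = series, lm_fit = fit
    ),
    class = "rhythm_fit"
  )
  ext <- curve_extrema(out)
  out$magnitude <- ext$magnitude
  out$orthophase <- ext$orthophase
  out$bathyphase <- ext$bathyphase
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent rhythm and zero-amplitude significance tests
#'
#' For each candidate period, refits the single-period cosinor model and
#' reports its coefficient of determination (percent rhythm, PR) and the
#' classical zero-amplitude F test `F = (R^2/2) / ((1-R^2)/(n-3))` on
#' `(2, n-3)` degrees of freedom. The full multi-period model gives the
#' integrated percent rhythm (IPR, its R^2) and the integrated P value (IP,
#' overall F on `(2C, n-2C-1)` df). Because every single-period model is
#' nested in the full model, `IPR >= max_c PR_c` always.
#'
#' @inheritParams fit_cosinor
#' @return A list with `per_period` (tibble: period, pr, p_value), `ipr`,
#'   `ip`.
#' @export
rhythm_tests <- function(series, periods = c(8, 12, 24)) {
  check_hourly_series(series, require_complete = TRUE)
  n <- nrow(series)
  k <- length(periods)
  if (n <= 2 * k + 1) {
    abort("Too few observations for the zero-amplitude tests.",
      class = "rhythmlink_error_insufficient_data")
  }
  r2_of <- function(fit) {
    tss <- sum((fit$model$y - mean(fit$model$y))^2)
    if (tss == 0) return(0)
    1 - sum(fit$residuals^2) / tss
  }
  f_tail <- function(r2, df1, df2) {
    if (r2 >= 1) return(0)
    pf((r2 / df1) / ((1 - r2) / df2), df1, df2, lower.tail = FALSE)
  }
  per_period <- purrr::map(periods, function(t_c) {
    fit1 <- fit_design(series$value, build_design(series$hour, t_c))
    r2 <- r2_of(fit1)
    tibble::new_tibble(list(period = t_c, pr = r2,
                            p_value = f_tail(r2, 2, n - 3)), nrow = 1L)
  }) |> purrr::list_rbind()
  full <- fit_design(series$value, build_design(series$hour, periods))
  ipr <- r2_of(full)
  list(per_period = per_period, ipr = ipr,
       ip = f_tail(ipr, 2 * k, n - 2 * k - 1))
}

#' Magnitude, orthophase and bathyphase of the fitted curve
#'
#' Evaluates the full fitted multi-component curve on a regular grid over
#' one fundamental period (the LCM of the component periods) and reports
#' half the peak-to-trough range (magnitude) and the times of the maximum
#' (orthophase) and minimum (bathyphase). Ties are broken by the earliest
#' time. Closed forms exist only for single components, so a fine grid is
#' used throughout.
#'
#' @param fit A `rhythm_fit`.
#' @param grid_step Grid resolution in minutes (default 1).
#' @return A list with `magnitude`, `orthophase`, `bathyphase` (hours in
#'   `[0, fundamental_period)`).
#' @export
curve_extrema <- function(fit, grid_step = 1) {
  stopifnot(inherits(fit, "rhythm_fit"))
  grid <- seq(0, fit$fundamental_period - grid_step / 60, by = grid_step / 60)
  y <- eval_curve(fit, grid)
  list(
    magnitude = (max(y) - min(y)) / 2,
    orthophase = grid[which.max(y)],   # which.max takes the earliest tie
    bathyphase = grid[which.min(y)]
  )
}

#' Evaluate the fitted cosinor curve at arbitrary times
#'
#' @param fit A `rhythm_fit`.
#' @param times Hours at which to evaluate.
#' @return Numeric vector of fitted values.
#' @export
eval_curve <- function(fit, times) {
  y <- rep(fit$mesor, length(times))
  for (i in seq_len(nrow(fit$components))) {
    cmp <- fit$components[i, ]
    y <- y + cmp$amplitude * cos(2 * pi * (times - cmp$acrophase) / cmp$period)
  }
  y
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat("Multi-component cosinor fit (", x$n_obs, " hourly obs)\n", sep = "")
  cat(sprintf("  MESOR %.3f (SE %.3f); IPR %.3f; IP %.3g\n",
              x$mesor, x$mesor_se, x$ipr, x$ip))
  print(tidy(x))
  invisible(x)
}

#' Tidy a cosinor fit into one row per periodic component
#'
#' @param x A `rhythm_fit`.
#' @param ... Unused.
#' @return A tibble with `period`, `amplitude`, `amp_se`, `acrophase`,
#'   `phi_se`, `pr` (percent rhythm), `p_value` (zero-amplitude test).
#' @method tidy rhythm_fit
#' @export
tidy.rhythm_fit <- function(x, ...) {
  dplyr::select(x$components, "period", "amplitude", "amp_se",
                "acrophase", "phi_se", "pr", "p_value")
}

#' Model-level summary of a cosinor fit
#'
#' @param x A `rhythm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `mesor`, `mesor_se`, `ipr`, `ip`, `magnitude`,
#'   `orthophase`, `bathyphase`, `residual_variance`, `n_obs`.
#' @method glance rhythm_fit
#' @export
glance.rhythm_fit <- function(x, ...) {
  tibble::tibble(
    mesor = x$mesor, mesor_se = x$mesor_se, ipr = x$ipr, ip = x$ip,
    magnitude = x$magnitude, orthophase = x$orthophase,
    bathyphase = x$bathyphase, residual_variance = x$residual_variance,
    n_obs = x$n_obs
  )
}

#' One-row wide form of a cosinor fit
#'
#' Flattens a fit into the rhythm-parameter column vocabulary used by the
#' correlation stage and the CSV reports: `MESOR`, `MESOR_SE`, and per
#' period `T` the columns `Amp-T`, `Amp_SE-T`, `PHI-T`, `PHI_SE-T`, `PR-T`,
#' `P-T`, plus `IPR`, `IP`, `magnitude`, `orthophase`, `bathyphase`,
#' `n_obs`.
#'
#' @param fit A `rhythm_fit`.
#' @return A one-row tibble, id columns first.
#' @export
rhythm_fit_row <- function(fit) {
  stopifnot(inherits(fit, "rhythm_fit"))
  per <- unlist(purrr::map(seq_len(nrow(fit$components)), function(i) {
    cmp <- fit$components[i, ]
    setNames(
      list(cmp$amplitude, cmp$amp_se, cmp$acrophase, cmp$phi_se,
           cmp$pr, cmp$p_value),
      paste0(c("Amp-", "Amp_SE-", "PHI-", "PHI_SE-", "PR-", "P-"),
             format(cmp$period))
    )
  }), recursive = FALSE)
  cols <- c(
    list(participant_id = fit$participant_id, feature = fit$feature,
         week = fit$week, MESOR = fit$mesor, MESOR_SE = fit$mesor_se),
    per,
    list(IPR = fit$ipr, IP = fit$ip, magnitude = fit$magnitude,
         orthophase = fit$orthophase, bathyphase = fit$bathyphase,
         n_obs = fit$n_obs)
  )
  tibble::new_tibble(cols, nrow = 1L)
}

#' Fit cosinor models in windows around each survey week
#'
#' For each survey week `w`, selects the hours of weeks
#' `max(1, w-1) .. min(n_weeks, w+1)` (a 3-week window, truncated at the
#' study boundary), applies the missingness discard rule per
#' participant-feature-window, imputes the retained windows, and fits the
#' multi-component cosinor model. Each fit is tagged with `w`.
#'
#' @param streams Streams tibble (`participant_id`, `feature`, `hour`,
#'   `value`, `missing`).
#' @param survey_weeks Weeks to fit around (default `c(1, 6, 15)`).
#' @param window_radius Weeks on either side of the survey week (default 1).
#' @param periods Component periods (default `c(8, 12, 24)`).
#' @param max_missing Discard threshold per window (default 0.20).
#' @param n_weeks Study length in weeks; inferred from the data if `NULL`.
#' @return A list with `fits` (wide tibble, one [rhythm_fit_row()] per
#'   retained participant-feature-week) and `log` (per-window retention
#'   decisions).
#' @export
fit_windows <- function(streams, survey_weeks = c(1L, 6L, 15L),
                        window_radius = 1L, periods = c(8, 12, 24),
                        max_missing = 0.20, n_weeks = NULL) {
  if (is.null(n_weeks)) n_weeks <- ceiling((max(streams$hour) + 1) / 168)
  res <- purrr::map(sort(unique(as.integer(survey_weeks))), function(w) {
    lo <- week_hour_range(max(1L, w - window_radius))[["from"]]
    hi <- week_hour_range(min(as.integer(n_weeks), w + window_radius))[["to"]]
    win <- dplyr::filter(streams, .data$hour >= lo, .data$hour < hi) |>
      dplyr::mutate(window = w)
    sel <- select_streams(win, max_missing = max_missing)
    if (nrow(sel$retained) == 0) {
      return(list(fits = tibble::tibble(), log = sel$log))
    }
    fits <- sel$retained |>
      dplyr::group_by(.data$participant_id, .data$feature) |>
      dplyr::group_split() |>
      purrr::map(function(s) {
        s$week <- w
        rhythm_fit_row(fit_cosinor(s, periods = periods))
      }) |>
      purrr::list_rbind()
    list(fits = fits, log = sel$log)
  })
  list(fits = purrr::list_rbind(purrr::map(res, "fits")),
       log = purrr::list_rbind(purrr::map(res, "log")))
}
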
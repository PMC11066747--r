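test_that("design matrix rows match the trigonometric closed forms", {
  d <- build_design(c(0, 6, 12, 18), periods = 24)
  expect_equal(unname(d$x[1, ]), c(1, 1, 0), tolerance = 1e-12)
  expect_equal(unname(d$x[2, ]), c(1, 0, 1), tolerance = 1e-12)

  d3 <- build_design(0:23, periods = c(8, 12, 24))
  expect_equal(ncol(d3$x), 7)
  expect_equal(d3$fundamental_period, 24)

  expect_error(build_design(0:5, periods = c(8, 12, 24)),
               class = "rhythmlink_error_underdetermined")
  expect_error(build_design(0:23, periods = c(24, 24)),
               class = "rhythmlink_error_bad_periods")
})

test_that("noiseless single-component series are recovered exactly", {
  s <- make_cos_series(72, mesor = 10, amps = c(`24` = 2), acros = c(`24` = 14))
  fit <- fit_cosinor(s, periods = 24)
  expect_equal(fit$mesor, 10, tolerance = 1e-8)
  expect_equal(fit$components$amplitude, 2, tolerance = 1e-8)
  expect_equal(fit$components$acrophase, 14, tolerance = 1e-8)
  expect_equal(fit$components$pr, 1, tolerance = 1e-10)
  expect_lt(fit$residual_variance, 1e-20)
})

test_that("a constant series fits with zero amplitude and no significance", {
  s <- tibble::tibble(hour = 0:71, value = 5, missing = FALSE)
  fit <- fit_cosinor(s, periods = c(8, 12, 24))
  expect_equal(fit$mesor, 5, tolerance = 1e-10)
  expect_true(all(fit$components$amplitude < 1e-10))
  expect_equal(fit$ip, 1, tolerance = 1e-10)
  expect_equal(fit$magnitude, 0, tolerance = 1e-10)
  expect_equal(fit$orthophase, 0)   # earliest-time tie rule
})

test_that("coefficients agree with an independent normal-equations solve", {
  withr::with_seed(31, {
    for (i in 1:5) {
      n <- sample(100:500, 1)
      hour <- 0:(n - 1)
      y <- 10 + 2 * cos(2 * pi * (hour - 14) / 24) +
        1 * cos(2 * pi * (hour - 3) / 12) + rnorm(n, 0, 1)
      s <- tibble::tibble(hour = hour, value = y, missing = FALSE)
      fit <- fit_cosinor(s, periods = c(12, 24))
      oracle <- normal_equations_fit(y, hour, c(12, 24))
      got <- c(fit$mesor,
               fit$components$beta[1], fit$components$gamma[1],
               fit$components$beta[2], fit$components$gamma[2])
      expect_equal(got, unname(oracle), tolerance = 1e-8)
    }
  })
})

test_that("polar parameters follow the phase arithmetic", {
  v <- diag(c(0.04, 0.04))
  aligned <- component_parameters(2, 0, v, 24)
  expect_equal(aligned$amplitude, 2)
  expect_equal(aligned$acrophase, 0)

  quadrature <- component_parameters(0, -2, v, 24)
  expect_equal(quadrature$amplitude, 2)
  expect_equal(quadrature$acrophase, 18)   # peak of -2*sin at t = 18
})

test_that("delta-method SEs match the closed form for diagonal covariance", {
  # for cov = s^2 I: var(A) = s^2 and var(phi_rad) = s^2 / A^2, independent
  # algebra from the polar-transform gradients
  s2 <- 0.04
  cp <- component_parameters(1, 1, diag(c(s2, s2)), 24)
  expect_equal(cp$amp_se, sqrt(s2), tolerance = 1e-12)
  expect_equal(cp$phi_se, (24 / (2 * pi)) * sqrt(s2) / sqrt(2),
               tolerance = 1e-12)
})

test_that("zero amplitude leaves the acrophase SE undefined", {
  cp <- component_parameters(0, 0, diag(c(0.01, 0.01)), 24)
  expect_true(is.na(cp$phi_se))
  expect_equal(cp$amplitude, 0)
})

test_that("percent rhythm separates generating and absent periods", {
  s <- make_cos_series(72, amps = c(`24` = 2), acros = c(`24` = 14))
  rt <- rhythm_tests(s, periods = c(8, 12, 24))
  pr <- setNames(rt$per_period$pr, rt$per_period$period)
  expect_equal(unname(pr["24"]), 1, tolerance = 1e-10)
  expect_lt(pr["8"], 1e-10)
  expect_lt(rt$per_period$p_value[rt$per_period$period == 24], 1e-12)
  expect_equal(rt$ipr, 1, tolerance = 1e-10)
})

test_that("IPR dominates every single-period PR across random fits", {
  withr::with_seed(55, {
    for (i in 1:40) {
      n <- sample(c(168, 336), 1)
      y <- rnorm(n) + sample(0:3, 1) * cos(2 * pi * (0:(n - 1)) / 24)
      s <- tibble::tibble(hour = 0:(n - 1), value = y, missing = FALSE)
      rt <- rhythm_tests(s, periods = c(8, 12, 24))
      expect_gte(rt$ipr + 1e-12, max(rt$per_period$pr))
    }
  })
})

test_that("curve extrema match geometry and a fine-grid oracle", {
  s1 <- make_cos_series(72, amps = c(`24` = 2), acros = c(`24` = 14))
  f1 <- fit_cosinor(s1, periods = 24)
  expect_equal(f1$magnitude, 2, tolerance = 1e-6)
  expect_equal(f1$orthophase, 14, tolerance = 1 / 60)
  expect_equal(f1$bathyphase, 2, tolerance = 1 / 60)

  s2 <- make_cos_series(504, mesor = 10, amps = c(`24` = 2, `12` = 1),
                        acros = c(`24` = 14, `12` = 3))
  f2 <- fit_cosinor(s2, periods = c(12, 24))
  # brute-force 1-second grid on the generative curve
  g <- seq(0, 24 - 1 / 3600, by = 1 / 3600)
  yg <- 10 + 2 * cos(2 * pi * (g - 14) / 24) + cos(2 * pi * (g - 3) / 12)
  expect_equal(f2$magnitude, (max(yg) - min(yg)) / 2, tolerance = 1e-4)
  expect_lt(min(abs(f2$orthophase - g[which.max(yg)]),
                24 - abs(f2$orthophase - g[which.max(yg)])), 1 / 60)
  expect_lt(min(abs(f2$bathyphase - g[which.min(yg)]),
                24 - abs(f2$bathyphase - g[which.min(yg)])), 1 / 60)
})

test_that("time-shifted series shift phases and keep everything else", {
  s <- make_cos_series(504, mesor = 10, amps = c(`24` = 2, `12` = 1),
                       acros = c(`24` = 14, `12` = 3))
  f0 <- fit_cosinor(s, periods = c(12, 24))
  k <- 5
  shifted <- dplyr::mutate(s, hour = hour + k)
  fk <- fit_cosinor(shifted, periods = c(12, 24))
  expect_equal(fk$mesor, f0$mesor, tolerance = 1e-8)
  expect_equal(fk$components$amplitude, f0$components$amplitude,
               tolerance = 1e-8)
  expect_equal(fk$components$acrophase,
               (f0$components$acrophase + k) %% c(12, 24), tolerance = 1e-6)
  expect_equal(fk$components$pr, f0$components$pr, tolerance = 1e-10)
  expect_equal((f0$orthophase + k) %% 24, fk$orthophase, tolerance = 1 / 30)
})

test_that("window fits use 3-week windows truncated at the study edges", {
  streams <- dplyr::mutate(make_cos_series(16 * 168), participant_id = "p",
                           feature = "f", .before = 1)
  wf <- fit_windows(streams, survey_weeks = c(1, 6, 15))
  n_obs <- setNames(wf$fits$n_obs, wf$fits$week)
  expect_equal(unname(n_obs["1"]), 336)   # weeks 1-2 only
  expect_equal(unname(n_obs["6"]), 504)   # weeks 5-7
  expect_equal(unname(n_obs["15"]), 504)  # weeks 14-16
})

test_that("fully discarded windows are logged and produce no fit", {
  s <- make_cos_series(16 * 168)
  lo <- 4 * 168
  idx <- s$hour >= lo & s$hour < lo + 3 * 168
  gone <- sum(idx) * 0.5
  s$missing[which(idx)[seq_len(gone)]] <- TRUE
  s$value[s$missing] <- NA
  streams <- dplyr::mutate(s, participant_id = "p", feature = "f",
                           .before = 1)
  wf <- fit_windows(streams, survey_weeks = c(1, 6))
  expect_setequal(unique(wf$fits$week), 1)
  expect_equal(wf$log$decision[wf$log$window == 6], "discarded")
})
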
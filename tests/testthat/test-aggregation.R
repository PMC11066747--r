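test_that("Fisher combination matches the closed-form chi-square survival", {
  one <- fisher_combine(0.5)
  expect_equal(one$fisher_stat, -2 * log(0.5), tolerance = 1e-4)
  expect_equal(one$combined_p, 0.5, tolerance = 1e-12)

  none <- fisher_combine(c(1, 1))
  expect_equal(none$fisher_stat, 0)
  expect_equal(none$combined_p, 1)

  two <- fisher_combine(c(0.05, 0.05))
  expect_equal(two$fisher_stat, -4 * log(0.05), tolerance = 1e-10)
  expect_equal(two$combined_p, fisher_survival_oracle(c(0.05, 0.05)),
               tolerance = 1e-10)

  withr::with_seed(3, {
    for (i in 1:30) {
      p <- runif(sample(1:8, 1))
      expect_equal(fisher_combine(p)$combined_p, fisher_survival_oracle(p),
                   tolerance = 1e-10)
    }
  })
})

test_that("Fisher combination handles degenerate inputs", {
  expect_error(fisher_combine(numeric(0)), class = "rhythmlink_error_no_input")
  expect_error(fisher_combine(c(0.5, 1.2)), class = "rhythmlink_error_no_input")
  expect_warning(out <- fisher_combine(c(0, 0.5)), "clamped")
  expect_lt(out$combined_p, 1e-100)
})

test_that("decreasing any input p never increases the combined p", {
  withr::with_seed(8, {
    for (i in 1:20) {
      p <- runif(5, 0.01, 1)
      base <- fisher_combine(p)$combined_p
      j <- sample(5, 1)
      p[j] <- p[j] / 2
      expect_lte(fisher_combine(p)$combined_p, base)
    }
  })
})

test_that("combined p values are uniform under the null", {
  n_rep <- 10000
  withr::with_seed(14, {
    combined <- vapply(seq_len(n_rep), function(i) {
      fisher_combine(runif(6))$combined_p
    }, numeric(1))
  })
  # empirical CDF within the 95% Kolmogorov-Smirnov band around uniform
  d_stat <- max(abs(sort(combined) - (seq_len(n_rep) - 0.5) / n_rep)) +
    0.5 / n_rep
  expect_lte(d_stat, 1.358 / sqrt(n_rep))
})

toy_cells <- tibble::tibble(
  feature = "f", parameter = c("a", "b", "c"), week = 1L,
  r = c(0.3, -0.2, 0.5), p = c(0.01, 0.20, 0.04), n = 30L
)

test_that("aggregation averages only the significant coefficients", {
  agg <- aggregate_cells(toy_cells, alpha = 0.05)
  expect_equal(agg$C_agg, 0.4)   # mean of 0.3 and 0.5
  expect_equal(agg$combined_p,
               fisher_survival_oracle(c(0.01, 0.20, 0.04)),
               tolerance = 1e-10)
  expect_equal(agg$n_significant, 2)

  dull <- dplyr::mutate(toy_cells, p = c(0.3, 0.4, 0.5))
  agg2 <- aggregate_cells(dull, alpha = 0.05)
  expect_true(is.na(agg2$C_agg))  # blank when nothing is significant
  expect_gt(agg2$S_score, 0)

  single <- toy_cells[1, ]
  agg3 <- aggregate_cells(single, alpha = 0.05)
  expect_equal(agg3$C_agg, 0.3)
  expect_equal(agg3$combined_p, 0.01, tolerance = 1e-10)
})

test_that("cross-week combination averages defined C and re-combines p", {
  weekly <- dplyr::bind_rows(
    aggregate_cells(dplyr::mutate(toy_cells, week = 1L)),
    aggregate_cells(dplyr::mutate(toy_cells, r = c(0.2, 0.2, 0.2),
                                  p = c(0.04, 0.5, 0.6), week = 2L)),
    aggregate_cells(dplyr::mutate(toy_cells, r = c(0.3, 0.3, 0.3),
                                  p = c(0.01, 0.01, 0.9), week = 3L))
  )
  overall <- combine_weeks(weekly)
  expect_equal(overall$C_agg, mean(weekly$C_agg))
  expect_equal(overall$combined_p,
               fisher_survival_oracle(weekly$combined_p), tolerance = 1e-10)
  expect_equal(overall$scope, "overall")

  single <- combine_weeks(weekly[1, ])
  expect_equal(single$C_agg, weekly$C_agg[1])
  expect_equal(single$combined_p, weekly$combined_p[1], tolerance = 1e-10)

  null_w <- dplyr::mutate(weekly, combined_p = 1, C_agg = NA_real_)
  flat <- combine_weeks(null_w)
  expect_equal(flat$combined_p, 1)
  expect_equal(flat$S_score, 0)
  expect_true(is.na(flat$C_agg))
})

test_that("aggregation is invariant to cell and week permutations", {
  perm <- toy_cells[c(3, 1, 2), ]
  expect_equal(aggregate_cells(perm, key = "f")$combined_p,
               aggregate_cells(toy_cells, key = "f")$combined_p,
               tolerance = 1e-12)
  expect_equal(aggregate_cells(perm, key = "f")$C_agg,
               aggregate_cells(toy_cells, key = "f")$C_agg)
})

test_that("the full cascade aggregates both axes, weekly and overall", {
  withr::with_seed(10, {
    cells <- tidyr::expand_grid(feature = c("f1", "f2"),
                                parameter = c("pa", "pb", "pc"),
                                week = 1:3) |>
      dplyr::mutate(r = runif(dplyr::n(), -1, 1),
                    p = runif(dplyr::n()), n = 40L)
  })
  sc <- aggregate_scores(cells)
  expect_equal(nrow(dplyr::filter(sc$weekly, axis == "feature")), 2 * 3)
  expect_equal(nrow(dplyr::filter(sc$weekly, axis == "parameter")), 3 * 3)
  expect_equal(nrow(sc$overall), 2 + 3)
  # pooled alternative combines all cell p values of a key at once
  pooled <- aggregate_scores(cells, cross_week = "pooled")
  f1 <- dplyr::filter(pooled$overall, key == "f1")
  expect_equal(f1$combined_p,
               fisher_survival_oracle(cells$p[cells$feature == "f1"]),
               tolerance = 1e-10)
})

test_that("rankings sort by score with alphabetical tie-breaks", {
  scores <- tibble::tibble(
    axis = "feature", key = c("beta", "alpha", "gamma"), scope = "overall",
    C_agg = c(0.2, NA, -0.5), fisher_stat = 1, combined_p = 1,
    S_score = c(5, 2, 7), n_cells = 3L, n_significant = 1L
  )
  rep <- rank_report(scores, top_k = 10)
  expect_equal(rep$feature$by_significance$key, c("gamma", "beta", "alpha"))
  expect_equal(rep$feature$by_correlation$key, c("gamma", "beta", "alpha"))

  tied <- dplyr::mutate(scores, S_score = 3)
  expect_equal(rank_report(tied)$feature$by_significance$key,
               c("alpha", "beta", "gamma"))
  expect_equal(nrow(rank_report(scores, top_k = 2)$feature$by_significance), 2)
})
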
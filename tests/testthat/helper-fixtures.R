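# Small deterministic fixtures shared across test files.

# Noiseless cosinor series built directly from the generative equation,
# independent of the simulator.
make_cos_series <- function(n_hours, mesor = 10, amps = c(`24` = 2),
                            acros = c(`24` = 14)) {
  hour <- 0:(n_hours - 1)
  value <- rep(mesor, n_hours)
  for (t_c in names(amps)) {
    value <- value +
      amps[[t_c]] * cos(2 * pi * (hour - acros[[t_c]]) / as.numeric(t_c))
  }
  tibble::tibble(hour = hour, value = value, missing = FALSE)
}

# Independent normal-equations least-squares oracle (never calls the
# package's fitting path).
normal_equations_fit <- function(y, times, periods) {
  x <- cbind(1, do.call(cbind, lapply(periods, function(t_c) {
    cbind(cos(2 * pi * times / t_c), sin(2 * pi * times / t_c))
  })))
  drop(solve(crossprod(x), crossprod(x, y)))
}

# Textbook Pearson r and two-tailed p, written out from first principles.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t_stat), df = n - 2))
}

# Chi-square survival for Fisher's statistic via the closed-form series
# for even degrees of freedom: P(X > x) = exp(-x/2) * sum_{j<k} (x/2)^j / j!
fisher_survival_oracle <- function(p_values) {
  x <- -2 * sum(log(p_values))
  k <- length(p_values)
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}
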
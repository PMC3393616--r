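# Shared fixtures: small deterministic problems with closed-form oracles.

# exponential decay x' = -theta x, x(0) = 1: x(t) = exp(-theta t)
decay_fixture <- function(h = 0.05, tN = 1) {
  list(model = decay_model(),
       x0 = box(1, 1, "x"),
       search = box(0, 3, "theta"),
       settings = enclosure_settings(h = h, k = 4, alpha = 0.005, t0 = 0,
                                     tN = tN))
}

# measurement set consistent with theta* = 1 on the decay model
decay_data <- function(times = 1, lo = 0.3, hi = 0.4) {
  measurement_set(times, rep(1L, length(times)), lo, hi)
}

# dense-grid brute-force classifier for the decay model using the closed
# form x(t) = exp(-theta t): the oracle for classify_box
decay_oracle_classify <- function(theta_lo, theta_hi, data, ngrid = 2001) {
  th <- seq(theta_lo, theta_hi, length.out = ngrid)
  feasible <- TRUE
  for (i in seq_len(nrow(data))) {
    x <- exp(-th * data$time[i])
    if (all(x < data$lo[i]) || all(x > data$hi[i])) return("unfeasible")
    if (!all(x >= data$lo[i] & x <= data$hi[i])) feasible <- FALSE
  }
  if (feasible) "feasible" else "indeterminate"
}

# random interval in [-5, 5] with width >= 0
rand_interval <- function() {
  a <- sort(stats::runif(2, -5, 5))
  interval(a[1], a[2])
}

expect_interval_equal <- function(x, lo, hi, tol = 1e-12) {
  expect_equal(x$lo, lo, tolerance = tol)
  expect_equal(x$hi, hi, tolerance = tol)
}
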
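test_that("measurement sets validate and round-trip via CSV", {
  d <- measurement_set(c(2, 1), c(1L, 1L), c(0.1, 0.2), c(0.4, 0.5))
  expect_equal(d$time, c(1, 2))
  expect_equal(n_measurement_times(d), 2L)
  expect_error(measurement_set(1, 1, 2, 1), "lo > hi")
  expect_error(measurement_set(c(1, 1), c(1, 1), c(0, 0), c(1, 1)),
               "duplicate")
  f <- tempfile(fileext = ".csv")
  write_measurements_csv(d, f)
  back <- read_measurements_csv(f)
  expect_identical(back$lo, d$lo)
  unlink(f)
})

test_that("measurement times snap to the grid within h/2 and error beyond", {
  s <- enclosure_settings(h = 0.02, k = 4, alpha = 0.005, t0 = 0, tN = 7)
  expect_equal(setdesign:::grid_index(c(2, 4), s), c(100L, 200L))
  expect_equal(setdesign:::grid_index(1.25, s), 62L)  # snaps to 1.24
  expect_error(setdesign:::grid_index(7.5, s), "grid")
})

test_that("classification agrees with the closed-form decay oracle", {
  fx <- decay_fixture(h = 0.05)
  data <- decay_data()  # x(1) in [0.3, 0.4] -> theta in [0.916, 1.204]
  cases <- list(c(0.95, 1.15), c(0.2, 0.5), c(2, 2.5), c(0.8, 1.4),
                c(1.0, 1.18), c(0.93, 1.2), c(1.3, 1.6))
  for (cs in cases) {
    got <- classify_box(box(cs[1], cs[2], "theta"), fx$x0, fx$model, data,
                        fx$settings)
    want <- decay_oracle_classify(cs[1], cs[2], data)
    # the guaranteed enclosure may be conservative, never wrongly certain:
    if (got %in% c("feasible", "unfeasible")) expect_identical(got, want)
    else expect_true(want %in% c("indeterminate", "feasible"))
  }
})

test_that("very wide measurement bounds force a feasible classification", {
  fx <- decay_fixture(h = 0.05)
  wide <- measurement_set(1, 1L, -1e6, 1e6)
  expect_identical(classify_box(box(0.5, 1.5, "theta"), fx$x0, fx$model,
                                wide, fx$settings), "feasible")
})

test_that("SIVIA recovers the closed-form decay solution interval", {
  fx <- decay_fixture(h = 0.05)
  data <- decay_data()
  part <- sivia_estimate(fx$search, fx$x0, fx$model, data, eps = 0.005,
                         fx$settings)
  true_lo <- -log(0.4)
  true_hi <- -log(0.3)
  # guaranteed cover
  expect_lte(min(part$lo), true_lo)
  expect_gte(max(part$hi), true_hi)
  # Hausdorff-close: within eps plus enclosure slack
  expect_lt(true_lo - min(part$lo), 0.01)
  expect_lt(max(part$hi) - true_hi, 0.01)
  # theta* = 1 is inside the union
  expect_true(any(part$lo[, 1] <= 1 & part$hi[, 1] >= 1))
  # partition boxes are pairwise interior-disjoint
  n <- n_boxes(part)
  for (i in seq_len(n - 1))
    expect_true(all(part$hi[i, 1] <= part$lo[(i + 1):n, 1] + 1e-15 |
                    part$lo[i, 1] >= part$hi[(i + 1):n, 1] - 1e-15))
})

test_that("SIVIA soundness: consistent parameters are never discarded", {
  fx <- decay_fixture(h = 0.05)
  set.seed(11)
  for (rep in 1:5) {
    theta_true <- runif(1, 0.3, 2.5)
    xs <- exp(-theta_true * c(0.5, 1))
    data <- measurement_set(c(0.5, 1), c(1L, 1L), xs - 0.02, xs + 0.02)
    part <- sivia_estimate(fx$search, fx$x0, fx$model, data, eps = 0.01,
                           fx$settings)
    expect_true(any(part$lo[, 1] <= theta_true &
                    part$hi[, 1] >= theta_true))
  }
})

test_that("stopping rule keeps indeterminate boxes at or below eps", {
  fx <- decay_fixture(h = 0.05)
  data <- decay_data()
  part <- sivia_estimate(fx$search, fx$x0, fx$model, data, eps = 0.02,
                         fx$settings)
  ind <- part$status == "indeterminate"
  expect_true(all((part$hi - part$lo)[ind, 1] <= 0.02 + 1e-15))
  # eps wider than the search box: at most one bisection happens
  part2 <- sivia_estimate(box(0.9, 1.25, "theta"), fx$x0, fx$model, data,
                          eps = 1, fx$settings)
  expect_lte(n_boxes(part2), 2L)
})

test_that("empty result is valid and flagged", {
  fx <- decay_fixture(h = 0.05)
  # impossible measurement: x(1) in [2, 3] but x(t) <= 1 for theta >= 0
  data <- measurement_set(1, 1L, 2, 3)
  expect_message(
    part <- sivia_estimate(fx$search, fx$x0, fx$model, data, eps = 0.05,
                           fx$settings),
    "inconsistent")
  expect_equal(n_boxes(part), 0L)
})

test_that("state_bounds of a point parameter box equals propagate", {
  fx <- decay_fixture(h = 0.05)
  part <- setdesign:::new_partition(matrix(1, 1, 1), matrix(1, 1, 1),
                                    "feasible", 0.01, fx$search)
  sb <- state_bounds(part, fx$x0, fx$model, fx$settings)
  pr <- propagate(fx$model, fx$x0, box(1, 1, "theta"), fx$settings)
  expect_equal(sb$lo, pr$lo, tolerance = 1e-14)
  expect_equal(sb$hi, pr$hi, tolerance = 1e-14)
})

test_that("adding a parameter box never shrinks the state bounds", {
  fx <- decay_fixture(h = 0.05)
  p1 <- setdesign:::new_partition(matrix(0.9, 1, 1), matrix(1.0, 1, 1),
                                  "indeterminate", 0.1, fx$search)
  p2 <- setdesign:::new_partition(matrix(c(0.9, 1.2), 2, 1),
                                  matrix(c(1.0, 1.4), 2, 1),
                                  c("indeterminate", "indeterminate"), 0.1,
                                  fx$search)
  s1 <- state_bounds(p1, fx$x0, fx$model, fx$settings)
  s2 <- state_bounds(p2, fx$x0, fx$model, fx$settings)
  expect_true(all(s2$lo[, 1] <= s1$lo[, 1] + 1e-14))
  expect_true(all(s2$hi[, 1] >= s1$hi[, 1] - 1e-14))
})

test_that("partition JSON round-trips", {
  fx <- decay_fixture(h = 0.05)
  data <- decay_data()
  part <- sivia_estimate(fx$search, fx$x0, fx$model, data, eps = 0.05,
                         fx$settings)
  f <- tempfile(fileext = ".json")
  write_partition_json(part, f)
  back <- read_partition_json(f, part$eps, part$search)
  expect_identical(back$lo, part$lo)
  expect_identical(back$status, part$status)
  unlink(f)
})
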
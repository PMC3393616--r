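test_that("shifted measurements reproduce the worked r = 3 example exactly", {
  sm <- shifted_measurements(interval(3, 6), 1.5, 3)
  expect_identical(vapply(sm, `[[`, numeric(1), "lo"), c(3, 3.75, 4.5))
  expect_identical(vapply(sm, `[[`, numeric(1), "hi"), c(4.5, 5.25, 6))
  # r = 2: the two extreme intervals only
  sm2 <- shifted_measurements(interval(3, 6), 1.5, 2)
  expect_identical(vapply(sm2, `[[`, numeric(1), "lo"), c(3, 4.5))
  # R equal to the full range: all intervals identical
  sm3 <- shifted_measurements(interval(3, 6), 3, 4)
  for (iv in sm3) expect_interval_equal(iv, 3, 6)
  expect_error(shifted_measurements(interval(3, 6), 4, 3), "exceeds")
})

test_that("candidate_range takes the larger adjacent measurement width", {
  d <- measurement_set(c(2, 4, 6), c(1L, 1L, 1L), c(0, 0, 0), c(2, 3, 1.5))
  expect_equal(candidate_range(3, d, 1L), 3)
  expect_equal(candidate_range(5, d, 1L), 3)
  # before the first measurement the initial anchor (width 0) applies
  expect_equal(candidate_range(1, d, 1L, t0 = 0, x0_width = 0), 2)
  expect_error(candidate_range(7, d, 1L), "beyond the last")
  # case-study arithmetic: widths of the printed error intervals
  w <- c(13.6065 - (-8.2190), 14.9691 - (-11.3067), 10.5414 - (-7.6254))
  cs <- measurement_set(c(2, 4, 6), c(1L, 1L, 1L), c(0, 0, 0), w)
  expect_equal(candidate_range(3, cs, 1L), 26.2758)
  expect_equal(candidate_range(5, cs, 1L), 26.2758)
})

test_that("candidate intervals implement the adjacent-uncertainty rule", {
  # synthetic envelope on a coarse grid
  times <- seq(0, 4, by = 0.5)
  mk_env <- function(w) setdesign:::new_state_envelope(
    times, matrix(-w / 2, length(times), 1), matrix(w / 2, length(times), 1),
    "x")
  d <- measurement_set(c(1, 3), c(1L, 1L), c(-1, -1), c(1, 1))  # widths 2
  # envelope narrower than the measurement widths everywhere: nothing
  ci0 <- candidate_intervals(mk_env(rep(1, length(times))), d, 1L)
  expect_equal(nrow(ci0), 0L)
  # constant width equal to the measurement widths: the whole open gap
  # qualifies (the rule is inclusive)
  ci1 <- candidate_intervals(mk_env(rep(2, length(times))), d, 1L)
  expect_true(any(ci1$start <= 1.5 & ci1$end >= 2.5))
  # wide only in the middle of the gap
  w <- rep(0, length(times)); w[times > 1.4 & times < 2.6] <- 3
  ci2 <- candidate_intervals(mk_env(w), d, 1L)
  expect_equal(nrow(ci2), 1L)
  expect_equal(ci2$start, 1.5)
  expect_equal(ci2$end, 2.5)
  expect_error(candidate_intervals(mk_env(w), d, 2L), "no measurements")
})

test_that("centre estimation follows the quadratic-fit rule", {
  centers <- seq(1, 5)
  # symmetric with interior maximum -> midpoint of the span
  est <- estimate_center(centers, c(1, 4, 5, 4, 1))
  expect_equal(est$center, 3)
  expect_false(est$fallback)
  # strictly increasing volumes (convex-or-rising fit) -> rightmost sample
  est2 <- estimate_center(centers, c(1, 2, 4, 8, 16))
  expect_equal(est2$center, 5)
  expect_true(est2$fallback)
  # vertex clamped to the sampled span
  est3 <- estimate_center(centers, c(5, 4.2, 3.6, 3.2, 3.0))
  expect_gte(est3$center, 1)
  expect_lte(est3$center, 5)
  expect_error(estimate_center(centers, rep(0, 5)), "no consistent")
})

test_that("candidates built from decay data contain the true output", {
  fx <- decay_fixture(h = 0.05, tN = 2)
  theta_true <- 1
  xs <- exp(-theta_true * c(0.5, 1.5))
  data <- measurement_set(c(0.5, 1.5), c(1L, 1L), xs - 0.05, xs + 0.05)
  part <- sivia_estimate(fx$search, fx$x0, fx$model, data, eps = 0.01,
                         fx$settings)
  cache <- partition_envelopes(part, fx$x0, fx$model, fx$settings)
  cands <- build_candidates(cache, data, 1L, 1.0, r = 7,
                            settings = fx$settings)
  y_true <- exp(-theta_true * 1.0)
  expect_lte(cands$C_j - cands$R_j / 2, y_true)
  expect_gte(cands$C_j + cands$R_j / 2, y_true)
  # shifted intervals span the envelope: first and last touch its bounds
  sv <- attr(cands, "shift_volumes")[[1]]
  node <- setdesign:::cache_node(cache, 1.0)
  env_lo <- cache$envelope$lo[node, 1]
  env_hi <- cache$envelope$hi[node, 1]
  expect_equal(min(sv$center) - cands$R_j / 2, unname(env_lo),
               tolerance = 1e-12)
  expect_equal(max(sv$center) + cands$R_j / 2, unname(env_hi),
               tolerance = 1e-12)
  # adding the candidate to the data cannot grow the parameter volume
  pv0 <- parameter_volume(part)
  pv1 <- parameter_volume(attr(cands, "partitions")[[1]])
  expect_lte(pv1, pv0 + 1e-15)
})

test_that("candidate filtering equals seeded re-estimation on the toy", {
  # certificates accelerate classification by discarding some truly
  # unfeasible boxes early; for a box-by-box comparison both routes must
  # run without them
  fx <- decay_fixture(h = 0.05, tN = 2)
  fx$settings$certificates <- FALSE
  xs <- exp(-c(0.5, 1.5))
  data <- measurement_set(c(0.5, 1.5), c(1L, 1L), xs - 0.05, xs + 0.05)
  part <- sivia_estimate(fx$search, fx$x0, fx$model, data, eps = 0.01,
                         fx$settings)
  cache <- partition_envelopes(part, fx$x0, fx$model, fx$settings)
  cands <- build_candidates(cache, data, 1L, 1.0, r = 7,
                            settings = fx$settings)
  filt <- attr(cands, "partitions")[[1]]
  d2 <- add_measurement(data, 1.0, 1L, cands$C_j - cands$R_j / 2,
                        cands$C_j + cands$R_j / 2)
  brute <- sivia_estimate(fx$search, fx$x0, fx$model, d2, eps = 0.01,
                          fx$settings, seeds = part)
  expect_equal(parameter_volume(filt), parameter_volume(brute),
               tolerance = 1e-14)
  expect_equal(sort(filt$lo[, 1]), sort(brute$lo[, 1]), tolerance = 1e-15)
})
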
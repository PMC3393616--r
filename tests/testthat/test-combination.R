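make_part <- function(lo, hi, status = NULL, eps = 1, search = NULL) {
  lo <- as.matrix(lo); hi <- as.matrix(hi)
  if (is.null(status)) status <- rep("indeterminate", nrow(lo))
  if (is.null(search))
    search <- box(rep(-10, ncol(lo)), rep(10, ncol(lo)),
                  paste0("p", seq_len(ncol(lo))))
  setdesign:::new_partition(lo, hi, status, eps, search)
}

test_that("uniformize subdivides exactly and conserves volume", {
  p <- make_part(matrix(c(0, 0), 1), matrix(c(1, 1), 1))
  u <- uniformize(p, 0.6)
  expect_equal(n_boxes(u), 4L)
  expect_true(all((u$hi - u$lo) < 0.6))
  expect_equal(parameter_volume(u), parameter_volume(p))
  # already fine: identity
  u2 <- uniformize(u, 0.6)
  expect_equal(n_boxes(u2), 4L)
  expect_identical(sort(u2$lo[, 1]), sort(u$lo[, 1]))
})

test_that("partition intersection behaves as a set intersection", {
  a <- make_part(matrix(c(0, 0), 1), matrix(c(2, 2), 1))
  b <- make_part(matrix(c(1, 1), 1), matrix(c(3, 3), 1))
  i <- intersect_partitions(a, b)
  expect_equal(n_boxes(i), 1L)
  expect_equal(parameter_volume(i), 1)
  # idempotence as a point set
  aa <- intersect_partitions(a, a)
  expect_equal(parameter_volume(aa), parameter_volume(a))
  # disjoint partitions give the empty partition
  c2 <- make_part(matrix(c(5, 5), 1), matrix(c(6, 6), 1))
  e <- intersect_partitions(a, c2)
  expect_equal(n_boxes(e), 0L)
  expect_equal(parameter_volume(e), 0)
  expect_error(intersect_partitions(a, make_part(matrix(0, 1), matrix(1, 1))),
               "dimension mismatch")
  # feasible status requires both parents feasible
  af <- make_part(matrix(c(0, 0), 1), matrix(c(2, 2), 1), "feasible")
  expect_identical(intersect_partitions(af, b)$status, "indeterminate")
  expect_identical(intersect_partitions(af, af)$status, "feasible")
})

test_that("PV is monotone under intersection", {
  set.seed(3)
  for (rep in 1:20) {
    a <- make_part(matrix(runif(2, 0, 1), 1), matrix(runif(2, 1, 2), 1))
    b <- make_part(matrix(runif(2, 0, 1), 1), matrix(runif(2, 1, 2), 1))
    i <- intersect_partitions(a, b)
    expect_lte(parameter_volume(i),
               min(parameter_volume(a), parameter_volume(b)) + 1e-15)
  }
})

test_that("intersection equals brute-force joint estimation on the decay model", {
  fx <- decay_fixture(h = 0.05, tN = 2)
  fx$settings$certificates <- FALSE
  xs <- exp(-c(0.5, 1.0, 1.5))
  data <- measurement_set(0.5, 1L, xs[1] - 0.05, xs[1] + 0.05)
  part <- sivia_estimate(fx$search, fx$x0, fx$model, data, eps = 0.01,
                         fx$settings)
  # two candidate measurements
  m1 <- c(1.0, xs[2] - 0.03, xs[2] + 0.03)
  m2 <- c(1.5, xs[3] - 0.04, xs[3] + 0.04)
  p1 <- sivia_estimate(fx$search, fx$x0, fx$model,
                       add_measurement(data, m1[1], 1L, m1[2], m1[3]),
                       eps = 0.01, fx$settings, seeds = part)
  p2 <- sivia_estimate(fx$search, fx$x0, fx$model,
                       add_measurement(data, m2[1], 1L, m2[2], m2[3]),
                       eps = 0.01, fx$settings, seeds = part)
  brute <- sivia_estimate(fx$search, fx$x0, fx$model,
                          add_measurement(
                            add_measurement(data, m1[1], 1L, m1[2], m1[3]),
                            m2[1], 1L, m2[2], m2[3]),
                          eps = 0.01, fx$settings, seeds = part)
  inter <- intersect_partitions(p1, p2)
  expect_lt(abs(parameter_volume(inter) - parameter_volume(brute)), 1e-12)
  expect_lt(abs(parameter_width(inter, 1L) - parameter_width(brute, 1L)),
            1e-12)
  # three-way check
  m3 <- c(0.75, exp(-0.75) - 0.05, exp(-0.75) + 0.05)
  p3 <- sivia_estimate(fx$search, fx$x0, fx$model,
                       add_measurement(data, m3[1], 1L, m3[2], m3[3]),
                       eps = 0.01, fx$settings, seeds = part)
  brute3 <- sivia_estimate(fx$search, fx$x0, fx$model,
                           Reduce(function(d, m)
                             add_measurement(d, m[1], 1L, m[2], m[3]),
                             list(m1, m2, m3), data),
                           eps = 0.01, fx$settings, seeds = part)
  inter3 <- intersect_partitions(intersect_partitions(p1, p2), p3)
  expect_lt(abs(parameter_volume(inter3) - parameter_volume(brute3)), 1e-12)
})

test_that("combine folds intersections and bounds the envelope monotonely", {
  fx <- decay_fixture(h = 0.05, tN = 2)
  xs <- exp(-c(0.5, 2.0))
  data <- measurement_set(c(0.5, 2.0), c(1L, 1L), xs - 0.05, xs + 0.05)
  part <- sivia_estimate(fx$search, fx$x0, fx$model, data, eps = 0.01,
                         fx$settings)
  cache <- partition_envelopes(part, fx$x0, fx$model, fx$settings)
  cands <- suppressWarnings(
    build_candidates(cache, data, 1L, c(1.0, 1.5), r = 5,
                     settings = fx$settings))
  singles <- attr(cands, "partitions")
  # singleton subset: unchanged partition
  c1 <- combine(1L, singles, envelope = TRUE, cache = cache)
  expect_equal(parameter_volume(c1$partition),
               parameter_volume(singles[[1]]))
  # pair: combined envelope inside each single envelope
  c12 <- combine(c(1L, 2L), singles, envelope = TRUE, cache = cache)
  e1 <- setdesign:::hull_envelope_from_cache(cache,
                                             attr(singles[[1]], "base_ids"))
  expect_true(all(c12$envelope$lo[, 1] >= e1$lo[, 1] - 1e-12))
  expect_true(all(c12$envelope$hi[, 1] <= e1$hi[, 1] + 1e-12))
})

test_that("enumerate_designs visits all subsets with monotone PV chains", {
  fx <- decay_fixture(h = 0.05, tN = 2)
  xs <- exp(-c(0.5, 2.0))
  data <- measurement_set(c(0.5, 2.0), c(1L, 1L), xs - 0.05, xs + 0.05)
  part <- sivia_estimate(fx$search, fx$x0, fx$model, data, eps = 0.01,
                         fx$settings)
  cache <- partition_envelopes(part, fx$x0, fx$model, fx$settings)
  cands <- suppressWarnings(
    build_candidates(cache, data, 1L, c(0.75, 1.0, 1.5), r = 5,
                     settings = fx$settings))
  singles <- attr(cands, "partitions")
  best <- enumerate_designs(singles, 3L, "PV", fx$model, cache = cache)
  tab <- attr(best, "table")
  expect_equal(nrow(tab), choose(3, 1) + choose(3, 2) + choose(3, 3))
  # nested chains: adding a measurement never increases PV
  pv1 <- tab$value[tab$times == "0.75"]
  pv12 <- tab$value[tab$times == "0.75,1"]
  pv123 <- tab$value[tab$times == "0.75,1,1.5"]
  expect_lte(pv12, pv1 + 1e-15)
  expect_lte(pv123, pv12 + 1e-15)
  # best-per-size values are non-increasing
  expect_true(all(diff(best$value) <= 1e-15))
})
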
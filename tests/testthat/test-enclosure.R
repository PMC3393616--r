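test_that("Taylor coefficients reproduce closed-form series", {
  # x' = x at x = 1: coefficients 1, 1, 1/2, 1/6 (exp series); model it as
  # decay with theta = -1
  m <- decay_model()
  tc <- taylor_coefficients(m, box(1, 1, "x"), box(-1, -1, "theta"), 3)
  expv <- c(1, 1, 1 / 2, 1 / 6)
  for (j in 1:4) {
    expect_lte(tc[[j]]$lo, expv[j])
    expect_gte(tc[[j]]$hi, expv[j])
    expect_lt(width(interval(tc[[j]]$lo, tc[[j]]$hi)), 1e-12)
  }
  # zero dynamics: all coefficients beyond order 0 are exactly 0
  z <- ode_model("x", "theta", list(x = quote(0 * x)), observed = 1L)
  tz <- taylor_coefficients(z, box(2, 3, "x"), box(0, 1, "theta"), 3)
  for (j in 2:4) expect_lte(max(abs(c(tz[[j]]$lo, tz[[j]]$hi))), 1e-300)
})

test_that("Lotka-Volterra first Taylor coefficient matches hand evaluation", {
  lv <- lotka_volterra_model()
  tc <- taylor_coefficients(lv, box(c(50, 50), c(50, 50)),
                            box(c(1, 0.01, 1, 0.02), c(1, 0.01, 1, 0.02)),
                            2)
  # f(x) = (x1 (p1 - p2 x2), -x2 (p3 - p4 x1)) = (25, 0)
  expect_equal(midpoint(interval(tc[[2]]$lo[1], tc[[2]]$hi[1])), 25,
               tolerance = 1e-10)
  expect_equal(midpoint(interval(tc[[2]]$lo[2], tc[[2]]$hi[2])), 0,
               tolerance = 1e-10)
})

test_that("unsupported expression nodes are rejected by name", {
  expect_error(ode_model("x", "k", list(x = quote(sin(x) * k))),
               "sin")
})

test_that("a-priori enclosure validates and contains the step solution", {
  fx <- decay_fixture(h = 0.05)
  # constant rhs 0: the box itself validates
  z <- ode_model("x", "theta", list(x = quote(0 * x)), observed = 1L)
  B <- a_priori_enclosure(z, box(1, 2, "x"), box(0, 0, "theta"),
                          fx$settings)
  expect_lte(B$lo, 1)
  expect_gte(B$hi, 2)
  expect_lt(B$hi - B$lo, 1.01 + 0.1)
  # decay from [1,1]: solution over [0, h] is [e^-h, 1]
  B2 <- a_priori_enclosure(fx$model, box(1, 1, "x"), box(1, 1, "theta"),
                           fx$settings)
  expect_lte(B2$lo, exp(-0.05))
  expect_gte(B2$hi, 1)
  # pathologically stiff rhs with a large step: validation failure
  stiff <- ode_model("x", "lam", list(x = quote(lam * x * x)),
                     observed = 1L)
  big <- enclosure_settings(h = 1, k = 2, alpha = 0.005, t0 = 0, tN = 2)
  expect_error(a_priori_enclosure(stiff, box(10, 10, "x"),
                                  box(5, 5, "lam"), big),
               "validation failed")
})

test_that("EMV step encloses the linear-decay flow tightly", {
  m <- decay_model()
  s <- enclosure_settings(h = 0.01, k = 4, alpha = 0.005, t0 = 0, tN = 0.01)
  st <- emv_init(m, box(0.9, 1.1, "x"), box(1, 1, "theta"))
  out <- emv_step(m, st, s)
  expect_true(out$ok)
  lo_true <- 0.9 * exp(-0.01)
  hi_true <- 1.1 * exp(-0.01)
  expect_lte(out$hull[1, 1], lo_true)
  expect_gte(out$hull[1, 2], hi_true)
  # method-dependent slack stays tiny
  expect_lt(lo_true - out$hull[1, 1], 1e-8)
  expect_lt(out$hull[1, 2] - hi_true, 1e-8)
  # zero dynamics: box and frame unchanged
  z <- ode_model("x", "theta", list(x = quote(0 * x)), observed = 1L)
  stz <- emv_init(z, box(1, 2, "x"), box(0, 0, "theta"))
  outz <- emv_step(z, stz, s)
  expect_true(outz$ok)
  expect_equal(outz$hull[1, ], c(1, 2), tolerance = 1e-12)
})

test_that("propagate matches the closed-form decay solution", {
  fx <- decay_fixture(h = 0.05, tN = 1)
  env <- propagate(fx$model, box(0.9, 1.1, "x"), box(0.5, 1.5, "theta"),
                   fx$settings)
  expect_equal(env$times[1], 0)
  expect_equal(unname(env$lo[1, 1]), 0.9)
  # contains the exact reachable set at every grid time
  for (i in seq_along(env$times)) {
    t <- env$times[i]
    expect_lte(env$lo[i, 1], 0.9 * exp(-1.5 * t) + 1e-12)
    expect_gte(env$hi[i, 1], 1.1 * exp(-0.5 * t) - 1e-12)
  }
  # constant model stays constant
  z <- ode_model("x", "theta", list(x = quote(0 * x)), observed = 1L)
  envz <- propagate(z, box(1, 2, "x"), box(0, 1, "theta"), fx$settings)
  expect_equal(envz$lo[, 1], rep(1, 21), tolerance = 1e-10)
  expect_equal(envz$hi[, 1], rep(2, 21), tolerance = 1e-10)
})

test_that("halving the step does not widen the decay envelope", {
  w_at_1 <- vapply(c(0.1, 0.05, 0.025), function(h) {
    fx <- decay_fixture(h = h, tN = 1)
    env <- propagate(fx$model, box(0.9, 1.1, "x"), box(1, 1, "theta"),
                     fx$settings)
    n <- length(env$times)
    env$hi[n, 1] - env$lo[n, 1]
  }, numeric(1))
  expect_lte(w_at_1[2], w_at_1[1] + 1e-9)
  expect_lte(w_at_1[3], w_at_1[2] + 1e-9)
})

test_that("enlarging initial sets never shrinks the envelope", {
  fx <- decay_fixture(h = 0.05, tN = 1)
  env1 <- propagate(fx$model, box(0.95, 1.05, "x"), box(0.9, 1.1, "theta"),
                    fx$settings)
  env2 <- propagate(fx$model, box(0.9, 1.1, "x"), box(0.8, 1.2, "theta"),
                    fx$settings)
  expect_true(all(env2$lo[, 1] <= env1$lo[, 1] + 1e-12))
  expect_true(all(env2$hi[, 1] >= env1$hi[, 1] - 1e-12))
})

test_that("LV point propagation contains a high-accuracy reference trajectory", {
  lv <- lotka_volterra_model()
  s <- enclosure_settings(h = 0.02, k = 4, alpha = 0.005, t0 = 0, tN = 7)
  env <- propagate(lv, box(c(50, 50), c(50, 50), c("x1", "x2")),
                   box(c(1, 0.01, 1, 0.02), c(1, 0.01, 1, 0.02),
                       c("p1", "p2", "p3", "p4")), s)
  tr <- deSolve::ode(c(x1 = 50, x2 = 50), env$times,
                     function(t, y, p)
                       list(c(y[1] * (p[1] - p[2] * y[2]),
                              -y[2] * (p[3] - p[4] * y[1]))),
                     c(1, 0.01, 1, 0.02), rtol = 1e-12, atol = 1e-12)
  expect_true(all(tr[, 2] >= env$lo[, 1] - 1e-8 &
                  tr[, 2] <= env$hi[, 1] + 1e-8))
  expect_true(all(tr[, 3] >= env$lo[, 2] - 1e-8 &
                  tr[, 3] <= env$hi[, 2] + 1e-8))
})

test_that("envelope CSV round-trips bit-exactly", {
  fx <- decay_fixture(h = 0.25, tN = 1)
  env <- propagate(fx$model, box(0.9, 1.1, "x"), box(1, 1, "theta"),
                   fx$settings)
  f <- tempfile(fileext = ".csv")
  write_envelope_csv(env, f)
  back <- read_envelope_csv(f)
  expect_identical(back$lo, env$lo)
  expect_identical(back$hi, env$hi)
  expect_identical(back$times, env$times)
  unlink(f)
})
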
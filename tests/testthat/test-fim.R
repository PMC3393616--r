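test_that("coverage variance matches the normal quantile identity", {
  # centred on [-1, 1]: sigma = 1 / z_{0.95}
  s2 <- coverage_variance(interval(-1, 1), 0)
  expect_equal(sqrt(s2), 1 / qnorm(0.95), tolerance = 1e-8)
  # off-centre means concentrate mass toward the near edge: a smaller
  # sigma is required to keep 0.9 of the mass inside
  expect_lt(coverage_variance(interval(-1, 1), 0.5), s2)
  # a mean on the interval edge can never reach 0.9 coverage (sup is 0.5)
  expect_error(coverage_variance(interval(-1, 1), -1), "coverage")
  expect_error(coverage_variance(interval(2, 2), 2), "zero-width")
})

test_that("sampled coverage hits 0.9 within Monte-Carlo tolerance", {
  set.seed(123)
  iv <- interval(3, 8)
  for (mu in c(5.5, 4.2)) {
    s2 <- coverage_variance(iv, mu)
    x <- rnorm(1e5, mu, sqrt(s2))
    expect_equal(mean(x >= iv$lo & x <= iv$hi), 0.9, tolerance = 0.01)
  }
})

test_that("Gaussian characterization places means at the shift fractions", {
  d <- measurement_set(c(2, 4), c(1L, 1L), c(0, 10), c(4, 20))
  ch <- gaussian_characterization(d, c("l", "r"))
  expect_equal(ch$mu, c(1, 17.5))
  chc <- gaussian_characterization(d, "c")
  expect_equal(chc$mu, c(2, 15))
  expect_true(all(chc$sigma2 > 0))
})

test_that("sensitivities match closed forms and finite differences", {
  # x' = theta, x(0) = 0: S(t) = t
  m1 <- ode_model("x", "theta", list(x = quote(theta + 0 * x)),
                  observed = 1L)
  se1 <- sensitivities(m1, 0, c(theta = 2), seq(0, 1, by = 0.25))
  expect_equal(se1$S[, 1, 1], seq(0, 1, by = 0.25), tolerance = 1e-7)
  # x' = -theta x, x(0) = 1: S(t) = -t exp(-theta t)
  m2 <- decay_model()
  tt <- seq(0, 2, by = 0.5)
  se2 <- sensitivities(m2, 1, c(theta = 0.7), tt)
  expect_equal(se2$S[, 1, 1], -tt * exp(-0.7 * tt), tolerance = 1e-7)
  # finite-difference check on Lotka-Volterra (1e-4 relative)
  lv <- lotka_volterra_model()
  th <- c(p1 = 1, p2 = 0.01, p3 = 1, p4 = 0.02)
  tt <- c(0, 2, 4, 6)
  se <- sensitivities(lv, c(50, 50), th, tt, free = c("p2", "p4"))
  hstep <- 1e-6
  for (pn in c("p2", "p4")) {
    up <- th; up[pn] <- up[pn] + hstep
    dn <- th; dn[pn] <- dn[pn] - hstep
    xu <- setdesign:::point_trajectory(lv, c(50, 50), up, tt, rtol = 1e-12)
    xd <- setdesign:::point_trajectory(lv, c(50, 50), dn, tt, rtol = 1e-12)
    fd <- (xu[, 2] - xd[, 2]) / (2 * hstep)
    got <- se$S[, 1, pn]
    expect_equal(got[-1], fd[-1], tolerance = 1e-4)
  }
})

test_that("FIM is symmetric PSD and monotone when times are added", {
  lv <- lotka_volterra_model()
  th <- c(p1 = 1, p2 = 0.01, p3 = 1, p4 = 0.02)
  tt <- c(0, 2, 3, 4, 6)
  se <- sensitivities(lv, c(50, 50), th, tt, free = c("p2", "p4"))
  M1 <- fim(se, c(2, 4), c(1, 1))
  M2 <- fim(se, c(2, 4, 6), c(1, 1, 1))
  expect_equal(M1, t(M1))
  ev1 <- eigen(M1, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev1 >= -1e-8))
  # Loewner monotone: M2 - M1 is PSD
  dv <- eigen(M2 - M1, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(dv >= -1e-8))
  # single time, single parameter: s^2 / sigma^2
  se1 <- sensitivities(lv, c(50, 50), th, c(0, 2), free = "p2")
  s <- se1$S[2, 1, 1]
  expect_equal(fim(se1, 2, 4)[1, 1], s^2 / 4, tolerance = 1e-10)
})

test_that("ML fit recovers the truth from exact means and ignores scaling", {
  m <- decay_model()
  tt <- c(0.5, 1, 1.5)
  mu <- exp(-1.2 * tt)
  char <- data.frame(time = tt, component = 1L, mu = mu,
                     sigma2 = c(1, 2, 0.5), shift = "explicit")
  fit <- ml_fit(m, char, 1, c(theta = 0.8), n_starts = 3L)
  expect_equal(unname(fit$theta), 1.2, tolerance = 1e-4)
  char2 <- char
  char2$sigma2 <- char$sigma2 * 7
  fit2 <- ml_fit(m, char2, 1, c(theta = 0.8), n_starts = 3L)
  expect_equal(unname(fit2$theta), unname(fit$theta), tolerance = 1e-5)
})

test_that("D-optimal selection is exhaustive and characterization-sensitive", {
  lv <- lotka_volterra_model()
  cfg <- case_study_config("desk")
  data <- generate_initial_measurements(cfg)
  cands <- c(1.25, 2.25, 3, 3.75)
  sels <- lapply(list(c("c", "c", "c"), c("l", "l", "l"), c("r", "r", "r")),
                 function(sh) {
    char <- gaussian_characterization(data, sh)
    d_optimal_select(lv, char, cfg$x0, cands, 1L,
                     theta0 = c(p2 = 0.01, p4 = 0.02),
                     fixed = c(p1 = 1, p3 = 1))
  })
  for (s in sels) {
    expect_length(s$subset, 1L)
    expect_true(s$det > 0)
    expect_equal(nrow(s$table), 4L)
    expect_equal(dim(s$ellipsoid), c(2L, 2L))
  }
  # determinant grows with a second measurement (nested selections)
  char <- gaussian_characterization(data, "c")
  s2 <- d_optimal_select(lv, char, cfg$x0, cands, 2L,
                         theta0 = c(p2 = 0.01, p4 = 0.02),
                         fixed = c(p1 = 1, p3 = 1))
  expect_gte(s2$det, sels[[1]]$det - 1e-12)
})
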
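# Classical FIM / D-optimality comparator.
#
# The interval measurements carry no distributional assumption; to compare
# against classical design, each measurement interval is recharacterized as
# a Gaussian whose mean sits at a chosen position in the interval (left /
# centre / right) and whose variance gives the distribution probability
# 0.9 over the interval.  A weighted least-squares ML fit, sensitivity
# ODEs and the Fisher information matrix then drive exhaustive D-optimal
# subset selection.  Instability of the selected time points across the
# mean characterizations is the point of the comparison.

#' Variance matching a 0.9 coverage over an interval
#'
#' Solves `Phi((hi - mu)/sigma) - Phi((lo - mu)/sigma) = coverage` for
#' `sigma` by bracketed root finding (relative tolerance 1e-10).
#'
#' @param interval An `"interval"` with positive width.
#' @param mu The Gaussian mean (need not be centred).
#' @param coverage Target probability mass over the interval (default 0.9).
#' @return The variance `sigma^2`.
#' @export
coverage_variance <- function(interval, mu, coverage = 0.9) {
  if (width(interval) <= 0)
    stop("coverage variance undefined for a zero-width interval",
         call. = FALSE)
  stopifnot(is.finite(mu), coverage > 0, coverage < 1)
  f <- function(sigma)
    stats::pnorm((interval$hi - mu) / sigma) -
    stats::pnorm((interval$lo - mu) / sigma) - coverage
  w <- width(interval)
  lo <- w * 1e-6; hi <- w * 1e3
  if (f(lo) < 0)
    stop("no variance achieves the requested coverage (mu too far outside)",
         call. = FALSE)
  sigma <- stats::uniroot(f, c(lo, hi), tol = 1e-10 * w)$root
  sigma^2
}

#' Gaussian characterization of an interval measurement set
#'
#' Means are placed at a fraction of each interval (defaults: 0.25 for a
#' left shift `"l"`, 0.5 for centre `"c"`, 0.75 for right `"r"`), and
#' variances solve the 0.9-coverage condition.
#'
#' @param data A `"measurement_set"`.
#' @param shifts Character vector (length 1 or `nrow(data)`) of `"l"`,
#'   `"c"`, `"r"`, or a numeric vector of explicit means.
#' @param coverage Coverage level for [coverage_variance()].
#' @param positions Named fractions for the shift labels.
#' @return Data frame: `time`, `component`, `mu`, `sigma2`, `shift`.
#' @export
gaussian_characterization <- function(data, shifts = "c", coverage = 0.9,
                                      positions = c(l = 0.25, c = 0.5,
                                                    r = 0.75)) {
  n <- nrow(data)
  if (is.numeric(shifts)) {
    stopifnot(length(shifts) == n)
    mu <- shifts
    lab <- rep("explicit", n)
  } else {
    if (length(shifts) == 1L) shifts <- rep(shifts, n)
    stopifnot(length(shifts) == n, all(shifts %in% names(positions)))
    mu <- data$lo + positions[shifts] * (data$hi - data$lo)
    lab <- shifts
  }
  s2 <- vapply(seq_len(n), function(i)
    coverage_variance(interval(data$lo[i], data$hi[i]), mu[i], coverage),
    numeric(1))
  data.frame(time = data$time, component = data$component, mu = mu,
             sigma2 = s2, shift = lab)
}

# integrate the model at point parameters with deSolve
point_trajectory <- function(model, x0, theta, times, rtol = 1e-10) {
  names(theta) <- model$params
  out <- deSolve::ode(y = stats::setNames(x0, model$states), times = times,
                      func = model_derivs(model), parms = as.list(theta),
                      rtol = rtol, atol = rtol, method = "lsoda")
  out
}

#' Weighted maximum-likelihood parameter fit
#'
#' Minimizes the variance-weighted squared deviation between the measured
#' component's trajectory and the characterization means, by Nelder-Mead
#' local optimization from `n_starts` deterministic starts around `theta0`.
#'
#' @param model An `"ode_model"`.
#' @param char A characterization from [gaussian_characterization()].
#' @param x0 Numeric initial state.
#' @param theta0 Named start values for the free parameters.
#' @param fixed Named values of the fixed parameters.
#' @param n_starts Number of multi-starts (factors 1, 0.5, 2, 0.8, 1.25 on
#'   `theta0`, recycled).
#' @return List: `theta` (named optimum), `objective`, `convergence`.
#' @export
ml_fit <- function(model, char, x0, theta0, fixed = NULL, n_starts = 5L) {
  free <- names(theta0)
  stopifnot(all(c(free, names(fixed)) %in% model$params))
  tt <- sort(unique(c(0, char$time)))
  rows <- match(char$time, tt)
  obj <- function(th) {
    full <- c(th, fixed)[model$params]
    names(full) <- model$params
    tr <- suppressWarnings(
      try(point_trajectory(model, x0, full, tt, rtol = 1e-8),
          silent = TRUE))
    # a diverging trajectory aborts the integrator early (fewer rows)
    if (inherits(tr, "try-error") || nrow(tr) < length(tt) ||
        any(!is.finite(tr)))
      return(1e30)
    sum(vapply(seq_len(nrow(char)), function(i) {
      xi <- tr[rows[i], 1 + char$component[i]]
      (xi - char$mu[i])^2 / char$sigma2[i]
    }, numeric(1)))
  }
  fac <- c(1, 0.5, 2, 0.8, 1.25)
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- theta0 * fac[((s - 1L) %% length(fac)) + 1L]
    fit <- if (length(free) == 1L) {
      stats::optim(st, function(v) {
        names(v) <- free
        obj(v)
      }, method = "Brent", lower = st - 10 * abs(st) - 1,
      upper = st + 10 * abs(st) + 1,
      control = list(maxit = 500))
    } else {
      stats::optim(st, function(v) {
        names(v) <- free
        obj(v)
      }, method = "Nelder-Mead",
      control = list(maxit = 500, reltol = 1e-12))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e30)
    stop("ML fit failed: objective not finite at any start", call. = FALSE)
  theta <- best$par
  names(theta) <- free
  list(theta = theta, objective = best$value,
       convergence = best$convergence)
}

#' Sensitivity trajectories via the forward sensitivity ODE
#'
#' Integrates the coupled state/sensitivity system (the sensitivity matrix
#' obeys `S' = J S + A` with `J` the state Jacobian and `A` the parameter
#' Jacobian of the rhs, both obtained symbolically) with a point
#' integrator; `S(t0) = 0` (parameter-independent initial conditions).
#'
#' @param model An `"ode_model"`.
#' @param x0 Numeric initial state.
#' @param theta Full named parameter vector.
#' @param times Output time points (first element = t0).
#' @param free Names of the parameters to differentiate against (default
#'   all).
#' @param rtol Integrator tolerance.
#' @return List: `times`, `x` (times x n), `S` (array times x n x
#'   length(free)).
#' @export
sensitivities <- function(model, x0, theta, times, free = model$params,
                          rtol = 1e-10) {
  n <- model$n
  q <- length(free)
  Jex <- lapply(model$rhs, function(e)
    lapply(model$states, function(s) stats::D(e, s)))
  Aex <- lapply(model$rhs, function(e)
    lapply(free, function(p) stats::D(e, p)))
  parms <- as.list(theta)
  derivs <- function(t, y, parms) {
    xs <- y[seq_len(n)]
    Smat <- matrix(y[-seq_len(n)], n, q)
    env <- c(as.list(stats::setNames(xs, model$states)), parms)
    f <- vapply(model$rhs, function(e) eval(e, env), numeric(1))
    J <- matrix(vapply(unlist(Jex, recursive = FALSE),
                       function(e) eval(e, env), numeric(1)),
                n, n, byrow = TRUE)
    A <- matrix(vapply(unlist(Aex, recursive = FALSE),
                       function(e) eval(e, env), numeric(1)),
                n, q, byrow = TRUE)
    dS <- J %*% Smat + A
    list(c(f, as.vector(dS)))
  }
  y0 <- c(stats::setNames(x0, model$states), rep(0, n * q))
  out <- deSolve::ode(y0, times, derivs, parms, rtol = rtol, atol = rtol,
                      method = "lsoda")
  if (any(!is.finite(out))) stop("sensitivity integration failed",
                                 call. = FALSE)
  S <- array(out[, -(1:(n + 1)), drop = FALSE], dim = c(nrow(out), n, q),
             dimnames = list(NULL, model$states, free))
  list(times = out[, 1], x = out[, 2:(n + 1), drop = FALSE], S = S)
}

#' Fisher information matrix for the measured component
#'
#' `FIM = sum_t (1/sigma2_t) s(t)^T s(t)` with `s(t)` the sensitivity row
#' of the measured component at time `t`; symmetric positive semidefinite
#' by construction.
#'
#' @param sens Output of [sensitivities()].
#' @param times Measurement times to include.
#' @param sigma2 Variances, one per entry of `times`.
#' @param component Measured state index.
#' @return A `q x q` matrix.
#' @export
fim <- function(sens, times, sigma2, component = 1L) {
  q <- dim(sens$S)[3L]
  M <- matrix(0, q, q)
  for (i in seq_along(times)) {
    k <- which.min(abs(sens$times - times[i]))
    s <- sens$S[k, component, ]
    M <- M + tcrossprod(s) / sigma2[i]
  }
  (M + t(M)) / 2
}

# variance assigned to a candidate time: the larger of the variances of
# the two adjacent initial measurements (one-sided before the first)
candidate_variance <- function(t_j, char) {
  lt <- char$time[char$time < t_j]
  rt <- char$time[char$time > t_j]
  v <- c(if (length(lt)) char$sigma2[char$time == max(lt)],
         if (length(rt)) char$sigma2[char$time == min(rt)])
  if (length(v) == 0L) stop("candidate time outside characterized span",
                            call. = FALSE)
  max(v)
}

#' Exhaustive D-optimal candidate selection
#'
#' Fits the parameters by [ml_fit()] under a Gaussian characterization of
#' the initial measurements, then maximizes `det(FIM)` over all subsets of
#' `k` candidate times added to the base measurement times.  Candidate
#' variances copy the larger adjacent initial-measurement variance.  The
#' 95% confidence ellipsoid matrix (`FIM^{-1}` scaled by the chi-squared
#' quantile) is reported for the winning design.
#'
#' @param model An `"ode_model"`.
#' @param char Characterization of the initial measurements.
#' @param x0 Numeric initial state.
#' @param candidates Candidate times.
#' @param k Subset size.
#' @param theta0 Named free-parameter start values for the ML fit.
#' @param fixed Named fixed parameters.
#' @param component Measured state index.
#' @return List: `subset` (best times), `det`, `theta_ml`, `ellipsoid`
#'   (matrix `E` such that `(theta - theta_ml)' E^{-1} (theta - theta_ml)
#'   <= 1` is the 95% region), `table` (all subsets and determinants).
#' @export
d_optimal_select <- function(model, char, x0, candidates, k, theta0,
                             fixed = NULL, component = 1L) {
  stopifnot(k >= 1L, k <= length(candidates))
  fit <- ml_fit(model, char, x0, theta0, fixed)
  theta <- c(fit$theta, fixed)[model$params]
  names(theta) <- model$params
  tt <- sort(unique(c(0, char$time, candidates)))
  sens <- sensitivities(model, x0, theta, tt, free = names(fit$theta))
  base_t <- char$time
  base_v <- char$sigma2
  cand_v <- vapply(candidates, candidate_variance, numeric(1), char = char)
  subs <- utils::combn(seq_along(candidates), k)
  dets <- apply(subs, 2L, function(ix) {
    M <- fim(sens, c(base_t, candidates[ix]), c(base_v, cand_v[ix]),
             component)
    det(M)
  })
  if (all(!is.finite(dets)) || max(dets, na.rm = TRUE) <= 0)
    stop("parameters locally unidentifiable: singular FIM for all subsets",
         call. = FALSE)
  bi <- which.max(dets)
  best <- candidates[subs[, bi]]
  Mb <- fim(sens, c(base_t, best), c(base_v, cand_v[subs[, bi]]), component)
  q <- length(fit$theta)
  ellipsoid <- solve(Mb) * stats::qchisq(0.95, q)
  tab <- data.frame(times = apply(subs, 2L, function(ix)
    paste(candidates[ix], collapse = ",")), det = dets)
  list(subset = best, det = dets[bi], theta_ml = fit$theta,
       ellipsoid = ellipsoid, table = tab)
}
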
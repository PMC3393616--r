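# Guaranteed enclosure of ODE solutions on a uniform grid.
#
# Each grid step is a k-th order interval Taylor step: a first-order
# fixed-point argument validates an a-priori enclosure of the solution over
# the step (inflating the candidate's deviation by 1+alpha between
# attempts), the truncated Taylor series propagates the box midpoint, and
# the deviation is pushed through the interval Jacobian of the truncated
# Taylor map in a QR-preconditioned frame (mean-value / EMV evaluation) to
# mitigate the wrapping effect.  When a step cannot be validated at the grid
# step size it is retried at halved sub-steps up to a configurable depth.

#' Enclosure settings
#'
#' @param h Grid step size (time units).
#' @param k Taylor expansion order (`>= 1`).
#' @param alpha Inflation factor applied to the candidate a-priori
#'   enclosure's deviation between validation attempts.
#' @param t0,tN Integration window; `(tN - t0) / h` must be integral.
#' @param max_inflate Maximum inflation/validation attempts per step.
#' @param max_halvings Maximum number of step-halvings when a step fails to
#'   validate at size `h`.
#' @param substep_budget Maximum attempted (sub)steps per trajectory
#'   enclosure; exhausting it counts as an enclosure failure.
#' @param state_cap Magnitude cap on enclosure bounds; exceeding it counts
#'   as an enclosure failure.
#' @param certificates Use growth-rate certificates (when the model declares
#'   them) for sound early discards during classification.
#' @return An object of class `"enclosure_settings"`.
#' @export
enclosure_settings <- function(h, k = 4L, alpha = 0.005, t0 = 0, tN,
                               max_inflate = 10L, max_halvings = 12L,
                               substep_budget = 5e4, state_cap = 1e12,
                               certificates = TRUE) {
  stopifnot(h > 0, k >= 1, alpha > 0, t0 < tN)
  ngrid <- round((tN - t0) / h)
  if (abs(ngrid - (tN - t0) / h) > 1e-8)
    stop("(tN - t0) / h must be an integer", call. = FALSE)
  structure(list(h = h, k = as.integer(k), alpha = alpha, t0 = t0, tN = tN,
                 ngrid = as.integer(ngrid), max_inflate = as.integer(max_inflate),
                 max_halvings = as.integer(max_halvings),
                 substep_budget = substep_budget, state_cap = state_cap,
                 certificates = isTRUE(certificates)),
            class = "enclosure_settings")
}

settings_cpp <- function(s) {
  list(h = s$h, k = s$k, alpha = s$alpha, max_inflate = s$max_inflate,
       max_halvings = s$max_halvings, substep_budget = s$substep_budget,
       state_cap = s$state_cap, certificates = s$certificates)
}

grid_times <- function(s) s$t0 + s$h * (0:s$ngrid)

# snap times to grid indices; error when off by more than h/2
grid_index <- function(times, s) {
  gi <- round((times - s$t0) / s$h)
  off <- abs(times - (s$t0 + gi * s$h))
  bad <- off > s$h / 2 + 1e-9 | gi < 0 | gi > s$ngrid
  if (any(bad))
    stop("time(s) ", paste(times[bad], collapse = ", "),
         " not within h/2 of a grid point in [t0, tN]", call. = FALSE)
  as.integer(gi)
}

#' Validated Taylor coefficients of the ODE solution
#'
#' Coefficient `j` encloses the scaled derivative `x^(j)/j!` of the solution
#' through any initial value in `x` with any parameter value in `theta`,
#' generated by running the model tape through the Taylor recurrences in
#' outward-rounded interval arithmetic.
#'
#' @param model An `"ode_model"`.
#' @param x State box (dimension `n`).
#' @param theta Parameter box (dimension `p`).
#' @param order Highest coefficient order (`>= 1`).
#' @return List of `order + 1` state-space boxes, one per coefficient.
#' @export
taylor_coefficients <- function(model, x, theta, order) {
  stopifnot(order >= 1)
  res <- cpp_taylor_coefficients(model$tape, aug_matrix(model, x, theta),
                                 as.integer(order))
  if (!res$ok)
    stop("interval evaluation failed (division by an interval containing 0)",
         call. = FALSE)
  lapply(seq_len(order + 1L), function(j)
    box(res$lo[j, seq_len(model$n)], res$hi[j, seq_len(model$n)],
        model$states))
}

#' A-priori enclosure of one integration step
#'
#' Returns a box validated (by a first-order fixed-point check) to contain
#' the solution over `[t, t + h]` for every initial value in `x` and every
#' parameter in `theta`.  The candidate enclosure's deviation from its
#' midpoint is inflated by `1 + alpha` before each validation attempt.
#'
#' @inheritParams taylor_coefficients
#' @param settings An `"enclosure_settings"`.
#' @return A state-space box.
#' @export
a_priori_enclosure <- function(model, x, theta, settings) {
  res <- cpp_a_priori(model$tape, cbind(x$lo, x$hi), cbind(theta$lo, theta$hi),
                      settings_cpp(settings))
  if (!res$ok)
    stop("step validation failed; reduce h", call. = FALSE)
  box(res$box[, 1L], res$box[, 2L], model$states)
}

#' Initialize / advance the mean-value (EMV) transition state
#'
#' `emv_init()` builds the preconditioned transition state (midpoint, frame,
#' deviation) for a joint state-parameter box; `emv_step()` advances it by
#' one grid step `h` and returns the new enclosure.  Parameters ride along
#' as augmented states with zero dynamics, so one mean-value propagation
#' handles the joint (x, theta) dependence.
#'
#' @inheritParams a_priori_enclosure
#' @return `emv_init()`: a transition-state list (`mid`, `frame`, `dev`,
#'   `hull`).  `emv_step()`: the updated transition state with entries `ok`
#'   (logical) and `hull`; the box `hull` contains every true solution at
#'   `t + h`.
#' @export
emv_init <- function(model, x, theta) {
  cpp_emv_init(model$tape, cbind(x$lo, x$hi), cbind(theta$lo, theta$hi))
}

#' @rdname emv_init
#' @param state A transition state from [emv_init()] or a previous
#'   [emv_step()].
#' @export
emv_step <- function(model, state, settings) {
  res <- cpp_emv_step(model$tape, state, settings_cpp(settings))
  if (!res$ok)
    warning("EMV step could not be validated", call. = FALSE)
  res
}

emv_hull_box <- function(model, state) {
  box(state$hull[, 1L], state$hull[, 2L], model$states)
}

new_state_envelope <- function(times, lo, hi, states) {
  colnames(lo) <- colnames(hi) <- states
  structure(list(times = times, lo = lo, hi = hi, states = states),
            class = "state_envelope")
}

#' @export
print.state_envelope <- function(x, ...) {
  cat(sprintf("state_envelope: %d grid times in [%g, %g], states: %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(x$states, collapse = ", ")))
  invisible(x)
}

#' Guaranteed solution envelope over the full time grid
#'
#' Repeats a-priori enclosure + EMV step over the uniform grid, returning
#' the per-grid-time enclosure of all trajectories started anywhere in `x0`
#' with parameters anywhere in `theta`.
#'
#' @inheritParams a_priori_enclosure
#' @param x0 Initial state box (zero widths encode exactly known initial
#'   conditions).
#' @return A `"state_envelope"` with one state-space box per grid time; the
#'   envelope at `t0` equals `x0`.
#' @export
propagate <- function(model, x0, theta, settings) {
  res <- cpp_propagate(model$tape, cbind(x0$lo, x0$hi),
                       cbind(theta$lo, theta$hi),
                       settings$ngrid, settings_cpp(settings))
  if (!res$ok)
    stop(sprintf("enclosure step failed at t = %.6g; reduce h",
                 settings$t0 + res$fail_at * settings$h), call. = FALSE)
  new_state_envelope(grid_times(settings), res$lo, res$hi, model$states)
}

#' Extract the envelope interval of one component at one grid time
#' @param envelope A `"state_envelope"`.
#' @param component State index.
#' @param time Grid time (must be within `h/2` of a grid point).
#' @export
envelope_at <- function(envelope, component, time) {
  i <- which.min(abs(envelope$times - time))
  interval(envelope$lo[i, component], envelope$hi[i, component])
}

envelope_widths <- function(envelope, component) {
  envelope$hi[, component] - envelope$lo[, component]
}

#' Write / read a state envelope as CSV
#'
#' Columns: `time`, then `lo`/`hi` per component; numbers carry 17
#' significant digits so the round-trip is bit-exact.
#'
#' @param envelope A `"state_envelope"`.
#' @param path File path.
#' @export
write_envelope_csv <- function(envelope, path) {
  cols <- c("time", as.vector(rbind(paste0(envelope$states, ".lo"),
                                    paste0(envelope$states, ".hi"))))
  n <- length(envelope$times)
  body <- vapply(seq_len(n), function(i) {
    v <- as.vector(rbind(envelope$lo[i, ], envelope$hi[i, ]))
    paste(fmt17(c(envelope$times[i], v)), collapse = ",")
  }, character(1))
  writeLines(c(paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_envelope_csv
#' @export
read_envelope_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "numeric")
  states <- sub("\\.lo$", "", names(df)[seq(2, ncol(df), 2)])
  lo <- as.matrix(df[, seq(2, ncol(df), 2), drop = FALSE])
  hi <- as.matrix(df[, seq(3, ncol(df), 2), drop = FALSE])
  new_state_envelope(df$time, unname(lo), unname(hi), states)
}
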
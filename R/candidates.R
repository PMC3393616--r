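# Candidate measurement construction: time points, ranges, centres.
#
# A candidate measurement is a triple (t_j, C_j, R_j): a future observation
# at time t_j assumed to land in [C_j - R_j/2, C_j + R_j/2].  Candidate
# times are taken where the estimated state envelope is at least as
# uncertain as the adjacent data measurements; the range R_j copies the
# larger adjacent measurement width (a conservative premise: a new
# measurement will not be less noisy than its neighbours); the centre C_j
# is placed where a simulated measurement of width R_j retains the largest
# consistent parameter volume, located by shifting the range across the
# envelope and fitting a quadratic to volume versus shift.

# anchor times/widths for a component: the initial condition acts as a
# zero-width anchor at t0, followed by the data measurements
anchors_for <- function(envelope, data, component) {
  dsub <- data[data$component == component, , drop = FALSE]
  if (nrow(dsub) < 1L)
    stop("component ", component, " has no measurements", call. = FALSE)
  t0 <- envelope$times[1L]
  w0 <- envelope$hi[1L, component] - envelope$lo[1L, component]
  data.frame(time = c(t0, dsub$time), width = c(w0, dsub$hi - dsub$lo))
}

#' Admissible candidate time intervals
#'
#' Returns the maximal runs of grid times, strictly between consecutive
#' anchor times (the exactly known initial condition and the measurement
#' times of the component), where the estimated envelope width is at least
#' the larger of the two adjacent anchor widths.  These are the times where
#' a new measurement is (conservatively) most informative.  Times beyond
#' the last measurement are never returned (no extrapolation rule).
#'
#' @param envelope A `"state_envelope"` from [state_bounds()].
#' @param data A `"measurement_set"` on the same grid.
#' @param component Measured state index.
#' @return Data frame with columns `start`, `end`, one row per maximal
#'   admissible interval.
#' @export
candidate_intervals <- function(envelope, data, component) {
  an <- anchors_for(envelope, data, component)
  times <- envelope$times
  w <- envelope_widths(envelope, component)
  ok <- rep(FALSE, length(times))
  for (i in seq_len(nrow(an) - 1L)) {
    inr <- which(times > an$time[i] & times < an$time[i + 1L])
    thr <- max(an$width[i], an$width[i + 1L])
    ok[inr] <- w[inr] >= thr
  }
  if (!any(ok)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = times[starts[keep]], end = times[ends[keep]])
}

#' Candidate measurement range (Eq.-style adjacent-width rule)
#'
#' The range of a candidate measurement at `t_j` is the larger of the two
#' adjacent measurement interval widths.  Before the first measurement the
#' exactly known initial condition acts as the left anchor (width
#' `x0_width`, zero for exact initial conditions); beyond the last
#' measurement there is no rule and an error is thrown.
#'
#' @param t_j Candidate time, strictly between two anchors.
#' @param data A `"measurement_set"`.
#' @param component Measured state index.
#' @param t0 Initial time (left anchor); set to `NULL` to require `t_j`
#'   between two data measurements.
#' @param x0_width Envelope width at `t0` (0 for exact initial conditions).
#' @return The range `R_j` (component units).
#' @export
candidate_range <- function(t_j, data, component, t0 = 0, x0_width = 0) {
  dsub <- data[data$component == component, , drop = FALSE]
  wd <- dsub$hi - dsub$lo
  if (t_j >= max(dsub$time))
    stop("candidate time ", t_j, " is beyond the last measurement",
         call. = FALSE)
  right <- min(which(dsub$time > t_j))
  if (any(dsub$time < t_j)) {
    left_w <- wd[max(which(dsub$time < t_j))]
  } else {
    if (is.null(t0) || t_j <= t0)
      stop("candidate time ", t_j, " is before the first measurement",
           call. = FALSE)
    left_w <- x0_width
  }
  max(left_w, wd[right])
}

#' Shifted simulated measurements across the estimated state range
#'
#' Generates `r` intervals of width `R_j` whose centres are equally spaced,
#' the first flush with the lower bound of the estimated state range and
#' the last flush with the upper bound.  Plain (non-outward) arithmetic:
#' these are constructed measurement definitions, not enclosures.
#'
#' @param state_range An `"interval"`: the estimated state bounds at the
#'   candidate time.
#' @param R_j Candidate range; must not exceed `width(state_range)`.
#' @param r Number of shifts (`>= 2`).
#' @return List of `r` `"interval"` objects.
#' @examples
#' shifted_measurements(interval(3, 6), 1.5, 3)  # [3,4.5] [3.75,5.25] [4.5,6]
#' @export
shifted_measurements <- function(state_range, R_j, r) {
  stopifnot(r >= 2, R_j > 0)
  if (R_j > width(state_range))
    stop("candidate range exceeds the estimated state range", call. = FALSE)
  c_lo <- state_range$lo + R_j / 2
  c_hi <- state_range$hi - R_j / 2
  lapply(seq_len(r), function(s) {
    cc <- c_lo + (s - 1) / (r - 1) * (c_hi - c_lo)
    interval(cc - R_j / 2, cc + R_j / 2)
  })
}

#' Centre-point estimation from shifted parameter volumes
#'
#' Fits volume ~ a c^2 + b c + d by least squares over the shift centres.
#' If the fit is concave (a < 0) the vertex -b/(2a), clamped to the sampled
#' centre span, is returned; otherwise the sampled centre with maximal
#' volume (fallback).  With r = 2 the argmax sample is returned directly.
#'
#' @param shift_centers Numeric vector of shift centre positions.
#' @param volumes Parameter volumes obtained with each shifted measurement.
#' @return List with `center`, `r_squared`, `coef` (quadratic coefficients
#'   `(a, b, d)` or `NULL`), and `fallback` (logical).
#' @export
estimate_center <- function(shift_centers, volumes) {
  stopifnot(length(shift_centers) == length(volumes),
            length(shift_centers) >= 2L)
  if (all(volumes == 0))
    stop("no consistent parameters at any shift", call. = FALSE)
  if (length(shift_centers) == 2L)
    return(list(center = shift_centers[which.max(volumes)],
                r_squared = NA_real_, coef = NULL, fallback = TRUE))
  fit <- stats::lm(volumes ~ shift_centers + I(shift_centers^2))
  cf <- stats::coef(fit)
  a <- cf[[3L]]; b <- cf[[2L]]; d <- cf[[1L]]
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((volumes - mean(volumes))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  if (is.finite(a) && a < 0) {
    v <- -b / (2 * a)
    v <- min(max(v, min(shift_centers)), max(shift_centers))
    list(center = v, r_squared = r2, coef = c(a = a, b = b, d = d),
         fallback = FALSE)
  } else {
    list(center = shift_centers[which.max(volumes)], r_squared = r2,
         coef = c(a = a, b = b, d = d), fallback = TRUE)
  }
}

#' Per-box envelopes of a partition (the combination fast path)
#'
#' Propagates the guaranteed enclosure once for every partition box and
#' caches the per-box per-grid-time hulls.  Because a box's envelope does
#' not depend on which measurements it is later compared against, adding a
#' candidate measurement to the data reduces to an overlap test between
#' each cached envelope and the new interval — the per-measurement
#' factorization of SIVIA classification that also underlies design
#' combination by parameter-set intersection.
#'
#' @inheritParams state_bounds
#' @return An object of class `"partition_envelopes"`: per-state matrices
#'   `lo[[s]]`, `hi[[s]]` (boxes x grid times, NA after an enclosure
#'   failure), `fail_node`, per-box free-dimension `volumes`, the grid
#'   `times`, `envelope` (the hull over boxes with validated full-window
#'   enclosures, as in [state_bounds()]), and the `partition`, `x0`,
#'   `model` and `settings` it was built from.
#' @export
partition_envelopes <- function(partition, x0, model, settings) {
  if (n_boxes(partition) == 0L)
    stop("empty partition", call. = FALSE)
  res <- cpp_partition_envelopes(model$tape, cbind(x0$lo, x0$hi),
                                 partition$lo, partition$hi,
                                 settings$ngrid, settings_cpp(settings))
  free <- which(width(partition$search) > 0)
  vols <- apply((partition$hi - partition$lo)[, free, drop = FALSE], 1, prod)
  ok <- res$fail_node < 0
  times <- grid_times(settings)
  env <- NULL
  if (any(ok)) {
    lo <- sapply(res$lo, function(m) apply(m[ok, , drop = FALSE], 2, min))
    hi <- sapply(res$hi, function(m) apply(m[ok, , drop = FALSE], 2, max))
    env <- new_state_envelope(times, lo, hi, model$states)
    attr(env, "n_used") <- sum(ok)
    attr(env, "n_failed") <- sum(!ok)
  }
  structure(list(lo = res$lo, hi = res$hi, fail_node = res$fail_node,
                 volumes = vols, times = times, envelope = env,
                 partition = partition, states = model$states,
                 x0 = x0, model = model, settings = settings),
            class = "partition_envelopes")
}

#' @export
print.partition_envelopes <- function(x, ...) {
  cat(sprintf(
    "partition_envelopes: %d boxes (%d with full-window enclosures)\n",
    length(x$volumes), sum(x$fail_node < 0)))
  invisible(x)
}

# grid node index (1-based) of a time in a cached envelope object; uses the
# same snapping rule as the measurement loader so that filtering and real
# re-estimation compare enclosures at the identical node
cache_node <- function(cache, time) grid_index(time, cache$settings) + 1L

# keep mask for one added measurement: a box survives unless its cached
# envelope at the node is disjoint from the interval; boxes with no
# enclosure at the node (earlier failure) are kept (conservative)
keep_mask <- function(cache, component, node, lo, hi) {
  blo <- cache$lo[[component]][, node]
  bhi <- cache$hi[[component]][, node]
  is.na(blo) | !(bhi < lo | blo > hi)
}

# subset a partition by a logical mask, recording parent ids
mask_partition <- function(partition, mask, cache = NULL, component = NULL,
                           node = NULL, mlo = NULL, mhi = NULL) {
  idx <- which(mask)
  status <- partition$status[idx]
  if (!is.null(cache)) {
    # a feasible box stays feasible only if its envelope is inside the new
    # measurement interval too; unknown (NA) envelopes demote to indeterminate
    blo <- cache$lo[[component]][idx, node]
    bhi <- cache$hi[[component]][idx, node]
    inside <- !is.na(blo) & blo >= mlo & bhi <= mhi
    status[status == "feasible" & !inside] <- "indeterminate"
  }
  out <- new_partition(partition$lo[idx, , drop = FALSE],
                       partition$hi[idx, , drop = FALSE],
                       status, partition$eps, partition$search)
  attr(out, "base_ids") <- idx
  out
}

# Restrict the base partition by one added measurement interval [lo, hi]
# for `component` at `time`.  Normally an overlap test on the cached
# envelopes (exactly seeded SIVIA, since boxes at or below eps are never
# re-bisected).  Feasible boxes wider than eps that turn indeterminate
# would be re-bisected by SIVIA, so those are re-run through the real
# seeded estimator against the full augmented data set.
restrict_partition <- function(cache, data, component, time, lo, hi) {
  part <- cache$partition
  node <- cache_node(cache, time)
  m <- keep_mask(cache, component, node, lo, hi)
  fd <- free_dims(part)
  widest <- apply((part$hi - part$lo)[, fd, drop = FALSE], 1, max)
  blo <- cache$lo[[component]][, node]
  bhi <- cache$hi[[component]][, node]
  inside <- !is.na(blo) & blo >= lo & bhi <= hi
  refine <- m & part$status == "feasible" & !inside & widest > part$eps
  if (!any(refine)) {
    p <- mask_partition(part, m, cache, component, node, lo, hi)
    return(list(partition = p, volume = sum(cache$volumes[m])))
  }
  plain <- mask_partition(part, m & !refine, cache, component, node, lo, hi)
  seeds <- new_partition(part$lo[refine, , drop = FALSE],
                         part$hi[refine, , drop = FALSE],
                         part$status[refine], part$eps, part$search)
  d2 <- add_measurement(data, time, component, lo, hi)
  ref <- sivia_estimate(part$search, cache$x0, cache$model, d2, part$eps,
                        cache$settings, seeds = seeds)
  merged <- new_partition(rbind(plain$lo, ref$lo), rbind(plain$hi, ref$hi),
                          c(plain$status, ref$status), part$eps,
                          part$search)
  list(partition = merged,
       volume = parameter_volume(plain) + parameter_volume(ref))
}

#' Build candidate measurements for a set of chosen times
#'
#' For each chosen time `t_j`: computes the range `R_j` from the adjacent
#' measurement widths, simulates `r` measurements by shifting `R_j` across
#' the estimated state bounds at `t_j`, evaluates the consistent parameter
#' volume with each shifted measurement added to the data (via the cached
#' per-box envelopes), and places the centre `C_j` by the quadratic-fit
#' rule of [estimate_center()].
#'
#' @param cache A `"partition_envelopes"` object for the base partition.
#' @param data The base `"measurement_set"`.
#' @param component Measured state index.
#' @param chosen_times Candidate times (normally inside
#'   [candidate_intervals()] output; a warning is issued otherwise).
#' @param r Number of shifts per candidate.
#' @param settings An `"enclosure_settings"` (for grid snapping).
#' @return A `"candidate_set"`: data frame with columns `t_j`, `component`,
#'   `C_j`, `R_j`, `r_squared`, `fallback`, plus attributes
#'   `shift_volumes` (per-candidate data frames of centre/volume) and
#'   `partitions` (per-candidate filtered partitions with the final
#'   candidate measurement added).
#' @export
build_candidates <- function(cache, data, component, chosen_times, r,
                             settings) {
  envelope <- cache$envelope
  if (is.null(envelope))
    stop("no box in the base partition admits a validated enclosure",
         call. = FALSE)
  ci <- candidate_intervals(envelope, data, component)
  covered <- vapply(chosen_times, function(t)
    any(t >= ci$start - settings$h / 2 & t <= ci$end + settings$h / 2),
    logical(1))
  if (!all(covered))
    warning("chosen time(s) ", paste(chosen_times[!covered], collapse = ", "),
            " outside the admissible candidate intervals", call. = FALSE)
  rows <- list()
  shift_tables <- list()
  parts <- list()
  for (t_j in chosen_times) {
    node <- cache_node(cache, t_j)
    R_j <- candidate_range(t_j, data, component, t0 = cache$times[1L],
                           x0_width = envelope$hi[1L, component] -
                                      envelope$lo[1L, component])
    st_range <- interval(envelope$lo[node, component],
                         envelope$hi[node, component])
    shifts <- shifted_measurements(st_range, R_j, r)
    centers <- vapply(shifts, midpoint, numeric(1))
    vols <- vapply(shifts, function(iv)
      restrict_partition(cache, data, component, t_j, iv$lo, iv$hi)$volume,
      numeric(1))
    est <- tryCatch(estimate_center(centers, vols), error = function(e)
      stop("candidate t_j = ", t_j, ": ", conditionMessage(e), call. = FALSE))
    C_j <- est$center
    parts[[as.character(t_j)]] <-
      restrict_partition(cache, data, component, t_j, C_j - R_j / 2,
                         C_j + R_j / 2)$partition
    rows[[as.character(t_j)]] <-
      data.frame(t_j = t_j, component = component, C_j = C_j, R_j = R_j,
                 r_squared = est$r_squared, fallback = est$fallback)
    shift_tables[[as.character(t_j)]] <-
      data.frame(center = centers, volume = vols)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("candidate_set", "data.frame"),
            shift_volumes = shift_tables, partitions = parts)
}

#' Write a candidate set to CSV with a JSON sidecar of shift volumes
#' @param candidates A `"candidate_set"`.
#' @param path CSV path; the sidecar gets extension `.shifts.json`.
#' @export
write_candidates_csv <- function(candidates, path) {
  df <- as.data.frame(candidates)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", "", path)
  sidecar <- paste0(sidecar, ".shifts.json")
  writeLines(jsonlite::toJSON(attr(candidates, "shift_volumes"),
                              digits = NA, auto_unbox = TRUE), sidecar)
  invisible(path)
}
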
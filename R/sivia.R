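# SIVIA set inversion over the parameter search box.
#
# A parameter box is classified by propagating the guaranteed enclosure and
# comparing the observed components against every measurement interval at
# its time: contained in all -> feasible, disjoint from one -> unfeasible
# (the propagation aborts at the first disjoint measurement), otherwise
# indeterminate.  SIVIA runs a FIFO queue from the search box, discarding
# unfeasible boxes, storing feasible ones, and bisecting indeterminate
# boxes wider than eps.  A box whose enclosure cannot be validated is kept
# as indeterminate (conservative).

#' Classify one parameter box against interval measurements
#'
#' @param theta Parameter box.
#' @param x0 Initial state box.
#' @param model An `"ode_model"`.
#' @param data A `"measurement_set"`; components must be observed states and
#'   times must lie within `h/2` of grid points.
#' @param settings An `"enclosure_settings"`.
#' @return One of `"feasible"`, `"unfeasible"`, `"indeterminate"`.  An
#'   enclosure failure classifies as indeterminate (with a warning).
#' @export
classify_box <- function(theta, x0, model, data, settings) {
  md <- meas_cpp(data, settings, model)
  code <- cpp_classify_box(model$tape, cert_tape(model, settings),
                           cbind(x0$lo, x0$hi), cbind(theta$lo, theta$hi),
                           md$gi, md$comp, md$lo, md$hi,
                           settings_cpp(settings))
  if (code == 3L) {
    warning("enclosure failed for a box; classified indeterminate",
            call. = FALSE)
    return("indeterminate")
  }
  c("unfeasible", "feasible", "indeterminate")[code + 1L]
}

cert_tape <- function(model, settings) {
  if (settings$certificates && model$positive_states && !is.null(model$gtape))
    model$gtape
  else NULL
}

new_partition <- function(lo, hi, status, eps, search, n_failed = 0L,
                          n_classified = NA_real_) {
  colnames(lo) <- colnames(hi) <- search$labels
  structure(list(lo = lo, hi = hi, status = status, eps = eps,
                 search = search, n_failed = n_failed,
                 n_classified = n_classified),
            class = "param_partition")
}

#' @export
print.param_partition <- function(x, ...) {
  cat(sprintf(
    "param_partition: %d feasible + %d indeterminate boxes (eps = %g)\n",
    sum(x$status == "feasible"), sum(x$status == "indeterminate"), x$eps))
  if (x$n_failed > 0)
    cat(sprintf("  (%d boxes kept indeterminate after enclosure failure)\n",
                x$n_failed))
  invisible(x)
}

#' Number of boxes in a partition
#' @param partition A `"param_partition"`.
#' @export
n_boxes <- function(partition) length(partition$status)

#' Extract partition boxes as a list of [box()] objects
#' @param partition A `"param_partition"`.
#' @param status Subset by status (default: all boxes).
#' @export
partition_boxes <- function(partition,
                            status = c("feasible", "indeterminate")) {
  idx <- which(partition$status %in% status)
  lapply(idx, function(i)
    box(partition$lo[i, ], partition$hi[i, ], partition$search$labels))
}

#' SIVIA parameter estimation from interval measurements
#'
#' Explores the a-priori search box with a FIFO queue: unfeasible boxes are
#' discarded, feasible boxes stored, and indeterminate boxes wider than
#' `eps` bisected along their widest dimension and re-queued.  Exactly
#' known parameters are fixed by making their search dimension zero-width;
#' an unknown initial condition can be appended as an extra search
#' dimension in a user-built model.
#'
#' @param search Parameter search box (the a-priori parameter set).
#' @param x0 Initial state box.
#' @inheritParams classify_box
#' @param eps Bisection threshold: indeterminate boxes are bisected while
#'   their widest dimension exceeds `eps`.
#' @param seeds Optional `"param_partition"` whose boxes seed the queue
#'   instead of `search`.  Sound whenever `seeds` came from a SIVIA run on
#'   a subset of `data` with the same model, `x0` and settings (adding
#'   measurements can only shrink the consistent set), and much faster.
#' @param eps_fail Refinement limit (`<= eps`) for boxes whose enclosure
#'   cannot be validated.  Such boxes carry no classification information,
#'   so they are bisected further than `eps` until the validated integrator
#'   recovers (or `eps_fail` is reached, at which point they are kept as
#'   indeterminate).  The default `eps` reproduces plain SIVIA stopping.
#' @return A `"param_partition"`.  An empty partition (model inconsistent
#'   with the data) is a valid result and is flagged with a message.
#' @export
sivia_estimate <- function(search, x0, model, data, eps, settings,
                           seeds = NULL, eps_fail = eps) {
  stopifnot(eps > 0, eps_fail > 0, eps_fail <= eps)
  md <- meas_cpp(data, settings, model)
  if (is.null(seeds)) {
    slo <- matrix(search$lo, nrow = 1)
    shi <- matrix(search$hi, nrow = 1)
  } else {
    stopifnot(inherits(seeds, "param_partition"))
    slo <- seeds$lo
    shi <- seeds$hi
    if (nrow(slo) == 0L)
      return(new_partition(slo, shi, character(0), eps, search))
  }
  res <- cpp_sivia(model$tape, cert_tape(model, settings),
                   cbind(x0$lo, x0$hi), slo, shi,
                   md$gi, md$comp, md$lo, md$hi, eps, eps_fail,
                   settings_cpp(settings))
  status <- c("unfeasible", "feasible", "indeterminate",
              "indeterminate")[res$status + 1L]
  part <- new_partition(res$lo, res$hi, status, eps, search,
                        n_failed = as.integer(res$n_failed),
                        n_classified = res$n_classified)
  if (n_boxes(part) == 0L)
    message("model inconsistent with data: no feasible or indeterminate boxes")
  part
}

#' Estimated state bounds from a parameter partition
#'
#' Runs the guaranteed enclosure for every feasible and indeterminate box
#' and hulls the per-box envelopes at each grid time, bounding measured and
#' unmeasured components alike.  Boxes whose enclosure cannot be validated
#' over the full window contribute nothing and are counted in the
#' `n_failed` attribute (their trajectories admit no validated bound).
#'
#' @param partition A non-empty `"param_partition"`.
#' @inheritParams classify_box
#' @return A `"state_envelope"` with attributes `n_used` and `n_failed`.
#' @export
state_bounds <- function(partition, x0, model, settings) {
  if (n_boxes(partition) == 0L)
    stop("empty partition: no state bounds", call. = FALSE)
  res <- cpp_state_bounds(model$tape, cbind(x0$lo, x0$hi),
                          partition$lo, partition$hi, settings$ngrid,
                          settings_cpp(settings))
  if (res$n_ok == 0L)
    stop("no partition box admitted a validated enclosure", call. = FALSE)
  ns <- seq_len(model$n)
  env <- new_state_envelope(grid_times(settings),
                            res$lo[, ns, drop = FALSE],
                            res$hi[, ns, drop = FALSE], model$states)
  attr(env, "n_used") <- res$n_ok
  attr(env, "n_failed") <- n_boxes(partition) - res$n_ok
  env
}

#' Serialize a partition to JSON (box records with a status field)
#' @param partition A `"param_partition"`.
#' @param path File path.
#' @export
write_partition_json <- function(partition, path) {
  write_boxes_json(partition_boxes(partition), path,
                   status = partition$status)
  invisible(path)
}

#' Read a partition written by [write_partition_json()]
#' @param path File path.
#' @param eps,search The bisection threshold and search box to attach.
#' @export
read_partition_json <- function(path, eps, search) {
  r <- read_boxes_json(path)
  lo <- do.call(rbind, lapply(r$boxes, `[[`, "lo"))
  hi <- do.call(rbind, lapply(r$boxes, `[[`, "hi"))
  new_partition(lo, hi, r$status, eps, search)
}
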
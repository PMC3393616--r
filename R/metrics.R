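# Scalar design metrics over partitions and envelopes.

free_dims <- function(partition) which(width(partition$search) > 0)

#' Parameter volume (PV)
#'
#' Sum over all partition boxes (feasible and indeterminate) of the product
#' of widths over the free parameter dimensions — the set-based analogue of
#' a confidence-region volume.  Dimensions fixed in the search box (zero
#' width) are excluded, otherwise PV would be identically zero whenever a
#' parameter is known exactly.  Optional per-dimension weights multiply the
#' widths (biological importance weighting); default 1.
#'
#' @param partition A `"param_partition"` (may be empty: PV 0).
#' @param weights Optional numeric weights, one per free dimension.
#' @return Nonnegative scalar.
#' @export
parameter_volume <- function(partition, weights = NULL) {
  if (n_boxes(partition) == 0L) return(0)
  fd <- free_dims(partition)
  w <- (partition$hi - partition$lo)[, fd, drop = FALSE]
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(fd))
    w <- sweep(w, 2L, weights, `*`)
  }
  sum(apply(w, 1L, prod))
}

#' Parameter-bound width (single or Euclidean-combined)
#'
#' For each requested dimension, the width of the hull of all partition
#' boxes projected to that dimension.  A single index returns that width;
#' several indices return the Euclidean norm of the widths.
#'
#' @param partition A non-empty `"param_partition"`.
#' @param indices Parameter dimensions: integer indices or names matching
#'   the search box labels.
#' @return Nonnegative scalar.
#' @export
parameter_width <- function(partition, indices) {
  if (n_boxes(partition) == 0L)
    stop("no consistent parameters", call. = FALSE)
  if (is.character(indices))
    indices <- match(indices, partition$search$labels)
  if (anyNA(indices) || length(indices) == 0L)
    stop("unknown parameter dimension", call. = FALSE)
  w <- vapply(indices, function(j)
    max(partition$hi[, j]) - min(partition$lo[, j]), numeric(1))
  if (length(w) == 1L) w else sqrt(sum(w^2))
}

#' State-bound metrics
#'
#' `kind = "max"`: the maximum over grid times of the upper envelope bound
#' (worst-case level of the component).  `kind = "range"`: the maximum over
#' grid times of the envelope width (worst-case uncertainty).
#'
#' @param envelope A `"state_envelope"`.
#' @param component State index.
#' @param kind `"max"` or `"range"`.
#' @return Scalar.
#' @export
state_metric <- function(envelope, component, kind = c("max", "range")) {
  kind <- match.arg(kind)
  if (kind == "max") max(envelope$hi[, component])
  else max(envelope$hi[, component] - envelope$lo[, component])
}

#' Parse a metric id
#'
#' Metric ids used in configuration and output tables:
#' `"PV"`, `"P:<name>"`, `"Pnorm:<name>,<name>"`, `"Xmax:<state>"`,
#' `"Xrange:<state>"`.
#'
#' @param id Metric id string.
#' @param model The `"ode_model"` (to resolve state names).
#' @return List with `id`, `needs_envelope` (logical) and `eval`, a
#'   function of `(partition, envelope)`.
#' @export
parse_metric <- function(id, model) {
  if (id == "PV")
    return(list(id = id, needs_envelope = FALSE,
                eval = function(partition, envelope = NULL)
                  parameter_volume(partition)))
  if (grepl("^P:", id)) {
    nm <- sub("^P:", "", id)
    return(list(id = id, needs_envelope = FALSE,
                eval = function(partition, envelope = NULL)
                  parameter_width(partition, nm)))
  }
  if (grepl("^Pnorm:", id)) {
    nms <- strsplit(sub("^Pnorm:", "", id), ",")[[1L]]
    return(list(id = id, needs_envelope = FALSE,
                eval = function(partition, envelope = NULL)
                  parameter_width(partition, nms)))
  }
  if (grepl("^X(max|range):", id)) {
    kind <- sub(":.*$", "", id)
    kind <- if (kind == "Xmax") "max" else "range"
    st <- sub("^X(max|range):", "", id)
    comp <- match(st, model$states)
    if (is.na(comp)) stop("unknown state '", st, "' in metric id", call. = FALSE)
    return(list(id = id, needs_envelope = TRUE,
                eval = function(partition, envelope)
                  state_metric(envelope, comp, kind)))
  }
  stop("unknown metric id '", id, "'", call. = FALSE)
}
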
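# Interval measurement sets.

#' Create a measurement set
#'
#' Time-indexed interval observations of measured components: each record
#' says the true output of component `component` at time `time` lies in
#' `[lo, hi]`.
#'
#' @param time Numeric vector of measurement times.
#' @param component Integer state indices (must be observed in the model
#'   the set is used with).
#' @param lo,hi Interval bounds, `lo <= hi`.
#' @return A `"measurement_set"` (a data frame with attribute `k`, the
#'   number of distinct measurement times).
#' @export
measurement_set <- function(time, component, lo, hi) {
  stopifnot(length(time) == length(component), length(time) == length(lo),
            length(time) == length(hi))
  if (any(lo > hi)) stop("measurement with lo > hi", call. = FALSE)
  df <- data.frame(time = as.double(time), component = as.integer(component),
                   lo = as.double(lo), hi = as.double(hi))
  df <- df[order(df$component, df$time), , drop = FALSE]
  for (cc in unique(df$component)) {
    tt <- df$time[df$component == cc]
    if (anyDuplicated(tt))
      stop("duplicate measurement times for component ", cc, call. = FALSE)
  }
  df <- df[order(df$time, df$component), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("measurement_set", "data.frame"),
            k = length(unique(df$time)))
}

#' Number of distinct measurement times
#' @param data A `"measurement_set"`.
#' @export
n_measurement_times <- function(data) attr(data, "k")

#' Append one measurement record
#' @param data A `"measurement_set"`.
#' @param time,component,lo,hi The new record.
#' @export
add_measurement <- function(data, time, component, lo, hi) {
  measurement_set(c(data$time, time), c(data$component, component),
                  c(data$lo, lo), c(data$hi, hi))
}

#' Read / write measurement sets as CSV (columns time, component, lo, hi)
#' @param data A `"measurement_set"`.
#' @param path File path.
#' @export
write_measurements_csv <- function(data, path) {
  body <- vapply(seq_len(nrow(data)), function(i)
    paste(c(fmt17(data$time[i]), data$component[i], fmt17(data$lo[i]),
            fmt17(data$hi[i])), collapse = ","), character(1))
  writeLines(c("time,component,lo,hi", body), path)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path)
  measurement_set(df$time, df$component, df$lo, df$hi)
}

# measurements in grid-index form for the C++ kernels (snapped to the grid)
meas_cpp <- function(data, settings, model = NULL) {
  if (!is.null(model) && !all(data$component %in% model$observed))
    stop("measurement component(s) not observed in the model", call. = FALSE)
  list(gi = grid_index(data$time, settings),
       comp = as.integer(data$component) - 1L,
       lo = data$lo, hi = data$hi)
}
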
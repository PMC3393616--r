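# Directed-rounding intervals and boxes.
#
# All arithmetic endpoints are nudged one unit in the last place outward by
# the compiled kernels, so the exact real-arithmetic result set is always
# contained in the returned interval.  The empty set is a distinct sentinel,
# never lo > hi; degenerate (zero-width) intervals are allowed everywhere so
# that exactly known quantities can flow through the same machinery.

#' Create a scalar interval
#'
#' @param lo,hi Finite (or infinite) numeric bounds with `lo <= hi`.
#' @return An object of class `"interval"`.
#' @examples
#' interval(1, 2)
#' width(interval(-1, 3))
#' @export
interval <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L,
            length(hi) == 1L)
  if (is.na(lo) || is.na(hi) || lo > hi)
    stop("invalid interval bounds: [", lo, ", ", hi, "]", call. = FALSE)
  structure(list(lo = as.double(lo), hi = as.double(hi), empty = FALSE),
            class = "interval")
}

#' The empty interval sentinel
#' @return An empty `"interval"` object.
#' @export
empty_interval <- function() {
  structure(list(lo = NA_real_, hi = NA_real_, empty = TRUE),
            class = "interval")
}

#' Test for the empty sentinel
#' @param x An `"interval"` or `"box"` object.
#' @export
is_empty <- function(x) isTRUE(x$empty)

#' @export
print.interval <- function(x, ...) {
  if (is_empty(x)) cat("<empty interval>\n")
  else cat(sprintf("[%.17g, %.17g]\n", x$lo, x$hi))
  invisible(x)
}

#' Interval width and midpoint
#' @param x An `"interval"` or `"box"` object.
#' @return `width()`: numeric width(s); `midpoint()`: numeric midpoint(s).
#' @export
width <- function(x) UseMethod("width")

#' @export
width.interval <- function(x) {
  if (is_empty(x)) return(0)
  x$hi - x$lo
}

#' @rdname width
#' @export
midpoint <- function(x) UseMethod("midpoint")

#' @export
midpoint.interval <- function(x) {
  if (is_empty(x)) stop("midpoint of empty interval", call. = FALSE)
  x$lo + 0.5 * (x$hi - x$lo)
}

#' Outward-rounded interval arithmetic
#'
#' Computes `a op b` so that the result contains `{x op y : x in a, y in b}`.
#' Division by an interval containing zero is an error (extended interval
#' splitting is out of scope).
#'
#' @param a,b Non-empty `"interval"` objects.
#' @param op One of `"add"`, `"sub"`, `"mul"`, `"div"`.
#' @return An `"interval"`.
#' @examples
#' interval_binary(interval(1, 2), interval(3, 4), "add")
#' @export
interval_binary <- function(a, b, op = c("add", "sub", "mul", "div")) {
  op <- match.arg(op)
  if (is_empty(a) || is_empty(b))
    stop("interval arithmetic on the empty interval", call. = FALSE)
  code <- switch(op, add = 1L, sub = 2L, mul = 3L, div = 4L)
  r <- cpp_iv_op(a$lo, a$hi, b$lo, b$hi, code)
  interval(r[1L], r[2L])
}

#' Create an interval box (Cartesian product of intervals)
#'
#' @param lo,hi Numeric vectors of lower and upper bounds, one per dimension.
#' @param labels Optional character vector of dimension names.
#' @return An object of class `"box"`.
#' @examples
#' box(c(0, 0), c(1, 2), labels = c("p1", "p2"))
#' @export
box <- function(lo, hi, labels = NULL) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == length(hi),
            length(lo) >= 1L)
  if (anyNA(lo) || anyNA(hi) || any(lo > hi))
    stop("invalid box bounds (lo > hi)", call. = FALSE)
  if (is.null(labels)) labels <- paste0("dim", seq_along(lo))
  stopifnot(length(labels) == length(lo))
  structure(list(lo = as.double(lo), hi = as.double(hi),
                 labels = as.character(labels), empty = FALSE),
            class = "box")
}

#' The empty box sentinel
#' @param labels Optional dimension names carried by the sentinel.
#' @export
empty_box <- function(labels = NULL) {
  structure(list(lo = numeric(0), hi = numeric(0),
                 labels = labels, empty = TRUE), class = "box")
}

#' @export
print.box <- function(x, ...) {
  if (is_empty(x)) { cat("<empty box>\n"); return(invisible(x)) }
  cat(sprintf("box (%d dims)\n", length(x$lo)))
  for (i in seq_along(x$lo))
    cat(sprintf("  %s: [%.17g, %.17g]\n", x$labels[i], x$lo[i], x$hi[i]))
  invisible(x)
}

#' @export
width.box <- function(x) {
  if (is_empty(x)) return(numeric(0))
  stats::setNames(x$hi - x$lo, x$labels)
}

#' @export
midpoint.box <- function(x) {
  if (is_empty(x)) stop("midpoint of empty box", call. = FALSE)
  stats::setNames(x$lo + 0.5 * (x$hi - x$lo), x$labels)
}

#' Box volume
#'
#' Product of the widths over all (or selected) dimensions.
#' @param b A `"box"`.
#' @param dims Dimensions to include (indices); default all.
#' @export
box_volume <- function(b, dims = seq_along(b$lo)) {
  if (is_empty(b)) return(0)
  prod(b$hi[dims] - b$lo[dims])
}

#' Bisect a box along its widest dimension
#'
#' Splits at the midpoint of the widest dimension; ties are broken by the
#' lowest dimension index.  The two halves partition the parent exactly.
#'
#' @param b A non-empty `"box"` with at least one positive-width dimension.
#' @return A list of two boxes.
#' @export
bisect_box <- function(b) {
  if (is_empty(b)) stop("cannot bisect the empty box", call. = FALSE)
  w <- b$hi - b$lo
  if (all(w == 0))
    stop("cannot bisect a degenerate (zero-volume) box", call. = FALSE)
  d <- which.max(w)  # lowest index on ties
  m <- b$lo[d] + 0.5 * (b$hi[d] - b$lo[d])
  left <- b; right <- b
  left$hi[d] <- m
  right$lo[d] <- m
  list(left, right)
}

#' Componentwise box intersection
#'
#' @param a,b Boxes of equal dimension.
#' @return The intersection box, or the empty sentinel if any component
#'   intersection is empty.
#' @export
intersect_box <- function(a, b) {
  if (is_empty(a) || is_empty(b)) return(empty_box(a$labels))
  if (length(a$lo) != length(b$lo))
    stop("box dimension mismatch", call. = FALSE)
  lo <- pmax(a$lo, b$lo)
  hi <- pmin(a$hi, b$hi)
  if (any(lo > hi)) return(empty_box(a$labels))
  box(lo, hi, a$labels)
}

#' Interval hull of a list of boxes
#'
#' Smallest box containing all inputs.
#'
#' @param boxes Non-empty list of boxes of equal dimension.
#' @return A `"box"`.
#' @export
hull <- function(boxes) {
  if (!is.list(boxes) || length(boxes) == 0L)
    stop("hull requires a non-empty list of boxes", call. = FALSE)
  boxes <- Filter(Negate(is_empty), boxes)
  if (length(boxes) == 0L)
    stop("hull of empty boxes is undefined", call. = FALSE)
  d <- length(boxes[[1L]]$lo)
  if (!all(vapply(boxes, function(b) length(b$lo), integer(1)) == d))
    stop("box dimension mismatch", call. = FALSE)
  lo <- do.call(pmin, lapply(boxes, `[[`, "lo"))
  hi <- do.call(pmax, lapply(boxes, `[[`, "hi"))
  box(lo, hi, boxes[[1L]]$labels)
}

# --- serialization ---------------------------------------------------------

fmt17 <- function(x) sprintf("%.17g", x)

#' Serialize boxes to JSON
#'
#' Each box becomes a record `{"dims": [...], "lo": [...], "hi": [...]}`;
#' numbers are written with 17 significant digits so the binary64 values
#' round-trip bit-exactly.
#'
#' @param boxes List of boxes.
#' @param path File path.
#' @param status Optional character vector (one entry per box) stored in a
#'   `"status"` field.
#' @export
write_boxes_json <- function(boxes, path, status = NULL) {
  recs <- lapply(seq_along(boxes), function(i) {
    b <- boxes[[i]]
    r <- list(dims = b$labels, lo = I(fmt17(b$lo)), hi = I(fmt17(b$hi)))
    if (!is.null(status)) r$status <- status[i]
    r
  })
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE), path)
  invisible(path)
}

#' Read boxes from JSON written by [write_boxes_json()]
#' @param path File path.
#' @return List with elements `boxes` (list of boxes) and `status`.
#' @export
read_boxes_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  boxes <- lapply(recs, function(r)
    box(as.double(unlist(r$lo)), as.double(unlist(r$hi)),
        unlist(r$dims)))
  status <- vapply(recs, function(r)
    if (is.null(r$status)) NA_character_ else r$status, character(1))
  list(boxes = boxes, status = status)
}

#' Serialize boxes to flat CSV (one row per box, lo/hi column pairs)
#' @inheritParams write_boxes_json
#' @export
write_boxes_csv <- function(boxes, path) {
  b1 <- boxes[[1L]]
  cols <- as.vector(rbind(paste0(b1$labels, ".lo"), paste0(b1$labels, ".hi")))
  rows <- vapply(boxes, function(b)
    paste(fmt17(as.vector(rbind(b$lo, b$hi))), collapse = ","), character(1))
  writeLines(c(paste(cols, collapse = ","), rows), path)
  invisible(path)
}

#' Read boxes from CSV written by [write_boxes_csv()]
#' @param path File path.
#' @return List of boxes.
#' @export
read_boxes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "numeric")
  labs <- sub("\\.lo$", "", names(df)[seq(1, ncol(df), 2)])
  lapply(seq_len(nrow(df)), function(i) {
    v <- as.double(df[i, ])
    box(v[seq(1, length(v), 2)], v[seq(2, length(v), 2)], labs)
  })
}
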
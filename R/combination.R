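# Multi-measurement designs via parameter-set intersection.
#
# The consistent parameter set for a combination of candidate measurements
# equals the intersection of the single-candidate sets, because SIVIA
# classification factorizes over measurements (a box's envelope does not
# depend on the data it is compared against).  Intersecting partitions is
# therefore a cheap substitute for re-running the estimation with all
# candidate measurements at once, and the package verifies the equivalence
# against brute-force runs in its test suite.

#' Uniformize a partition
#'
#' Bisects every box (feasible and indeterminate) until all widths are
#' strictly below `eps`, preserving the union as a point set exactly
#' (bisection splits at representable midpoints).  This makes boxes from
#' different partitions comparable in scale before intersection.
#'
#' @param partition A `"param_partition"`.
#' @param eps Target width.
#' @return A `"param_partition"` with the same point-set union.
#' @export
uniformize <- function(partition, eps) {
  stopifnot(eps > 0)
  lo <- partition$lo; hi <- partition$hi; status <- partition$status
  out_lo <- list(); out_hi <- list(); out_st <- character(0)
  queue_lo <- split(lo, row(lo)); queue_hi <- split(hi, row(hi))
  queue_st <- status
  # FIFO bisection; boxes already below eps pass straight through
  i <- 1L
  while (i <= length(queue_lo)) {
    blo <- queue_lo[[i]]; bhi <- queue_hi[[i]]
    w <- bhi - blo
    if (max(w) < eps) {
      out_lo[[length(out_lo) + 1L]] <- blo
      out_hi[[length(out_hi) + 1L]] <- bhi
      out_st <- c(out_st, queue_st[i])
    } else {
      d <- which.max(w)
      m <- blo[d] + 0.5 * (bhi[d] - blo[d])
      h1 <- bhi; h1[d] <- m
      l2 <- blo; l2[d] <- m
      queue_lo[[length(queue_lo) + 1L]] <- blo
      queue_hi[[length(queue_hi) + 1L]] <- h1
      queue_lo[[length(queue_lo) + 1L]] <- l2
      queue_hi[[length(queue_hi) + 1L]] <- bhi
      queue_st <- c(queue_st, queue_st[i], queue_st[i])
    }
    i <- i + 1L
  }
  new_partition(do.call(rbind, out_lo), do.call(rbind, out_hi), out_st,
                min(partition$eps, eps), partition$search)
}

#' Intersect two parameter partitions
#'
#' Pairwise box intersections with empty results dropped; an intersection
#' box is feasible iff both parents are feasible (conservative otherwise).
#' Associative and commutative up to box ordering; the union is exactly
#' the intersection of the two unions as point sets.
#'
#' @param a,b `"param_partition"` objects over the same search box.
#' @return A `"param_partition"` (possibly empty).
#' @export
intersect_partitions <- function(a, b) {
  if (ncol(a$lo) != ncol(b$lo))
    stop("partition dimension mismatch", call. = FALSE)
  # fast path: both partitions are row subsets of one base partition
  ia <- attr(a, "base_ids"); ib <- attr(b, "base_ids")
  if (!is.null(ia) && !is.null(ib)) {
    common <- intersect(ia, ib)
    ka <- match(common, ia); kb <- match(common, ib)
    st <- ifelse(a$status[ka] == "feasible" & b$status[kb] == "feasible",
                 "feasible", "indeterminate")
    out <- new_partition(a$lo[ka, , drop = FALSE], a$hi[ka, , drop = FALSE],
                         st, max(a$eps, b$eps), a$search)
    attr(out, "base_ids") <- common
    return(out)
  }
  d <- ncol(a$lo)
  fd <- free_dims(a)
  res_lo <- list(); res_hi <- list(); res_st <- character(0)
  for (i in seq_len(nrow(a$lo))) {
    ov <- rep(TRUE, nrow(b$lo))
    for (j in seq_len(d))
      ov <- ov & b$lo[, j] <= a$hi[i, j] & b$hi[, j] >= a$lo[i, j]
    for (k in which(ov)) {
      lo <- pmax(a$lo[i, ], b$lo[k, ])
      hi <- pmin(a$hi[i, ], b$hi[k, ])
      # pieces that are faces of neighbouring tiles carry no volume and
      # duplicate content already covered by the positive-volume pieces
      if (any(hi[fd] <= lo[fd])) next
      res_lo[[length(res_lo) + 1L]] <- lo
      res_hi[[length(res_hi) + 1L]] <- hi
      res_st <- c(res_st,
                  if (a$status[i] == "feasible" && b$status[k] == "feasible")
                    "feasible" else "indeterminate")
    }
  }
  if (length(res_lo) == 0L)
    return(new_partition(matrix(numeric(0), 0, d,
                                dimnames = list(NULL, a$search$labels)),
                         matrix(numeric(0), 0, d), character(0),
                         max(a$eps, b$eps), a$search))
  new_partition(do.call(rbind, res_lo), do.call(rbind, res_hi), res_st,
                max(a$eps, b$eps), a$search)
}

#' Evaluate one design combination
#'
#' Folds [intersect_partitions()] over the selected candidates' single
#' partitions, then derives the combined state bounds.
#'
#' @param candidate_ids Indices into `singles`.
#' @param singles List of single-candidate `"param_partition"` objects
#'   (identical base data and `eps`).
#' @param x0,model,settings As in [state_bounds()]; only needed when
#'   `envelope = TRUE`.
#' @param envelope Compute the combined state bounds (can be expensive).
#' @param cache Optional `"partition_envelopes"` of the base partition;
#'   when all singles are subsets of its partition the combined envelope
#'   is assembled from the cached per-box envelopes instead of
#'   re-propagating.
#' @return A `"design_combination"`: `candidate_ids`, `partition`,
#'   `envelope` (or NULL), `inconsistent` flag.
#' @export
combine <- function(candidate_ids, singles, x0 = NULL, model = NULL,
                    settings = NULL, envelope = FALSE, cache = NULL) {
  stopifnot(length(candidate_ids) >= 1L)
  part <- singles[[candidate_ids[1L]]]
  for (id in candidate_ids[-1L])
    part <- intersect_partitions(part, singles[[id]])
  env <- NULL
  if (envelope && n_boxes(part) > 0L) {
    ids <- attr(part, "base_ids")
    if (!is.null(cache) && !is.null(ids)) {
      env <- hull_envelope_from_cache(cache, ids)
    } else {
      if (is.null(model) && !is.null(cache)) {
        x0 <- cache$x0; model <- cache$model; settings <- cache$settings
      }
      env <- state_bounds(part, x0, model, settings)
    }
  }
  structure(list(candidate_ids = candidate_ids, partition = part,
                 envelope = env, inconsistent = n_boxes(part) == 0L),
            class = "design_combination")
}

# hull of cached per-box envelopes over a subset of base boxes (only boxes
# with validated full-window enclosures contribute, as in state_bounds)
hull_envelope_from_cache <- function(cache, ids) {
  ok <- ids[cache$fail_node[ids] < 0]
  if (length(ok) == 0L) return(NULL)
  n <- length(cache$lo)
  lo <- sapply(seq_len(n), function(s)
    apply(cache$lo[[s]][ok, , drop = FALSE], 2, min))
  hi <- sapply(seq_len(n), function(s)
    apply(cache$hi[[s]][ok, , drop = FALSE], 2, max))
  env <- new_state_envelope(cache$times, lo, hi, cache$states)
  attr(env, "n_used") <- length(ok)
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate candidate-subset designs and rank them by a metric
#'
#' Evaluates the metric for every subset of size 1..`k_c` of the candidate
#' partitions, using intersection instead of re-estimation.  All metrics in
#' this package measure uncertainty, so smaller is better; ties are broken
#' by the lexicographically smallest time vector (the enumeration order).
#'
#' @param singles Named list (names = candidate times) of single-candidate
#'   partitions.
#' @param k_c Maximum subset size.
#' @param metric A metric id (see [parse_metric()]) or parsed metric.
#' @param model The `"ode_model"`.
#' @param cache Optional `"partition_envelopes"` for envelope-based
#'   metrics on subsets of a common base partition.
#' @param all_subsets Return the full evaluation table as attribute
#'   `"table"`.
#' @return Data frame with one row per subset size: `size`, `times`
#'   (comma-separated), `value`.
#' @export
enumerate_designs <- function(singles, k_c, metric, model, cache = NULL,
                              all_subsets = TRUE) {
  stopifnot(k_c >= 1L, k_c <= length(singles))
  if (is.character(metric)) metric <- parse_metric(metric, model)
  nms <- names(singles)
  nc <- length(singles)
  rows <- list()
  eval_subset <- function(ids, part) {
    # an empty intersection is an inconsistent design: never ranked best
    if (n_boxes(part) == 0L) return(NA_real_)
    env <- NULL
    if (metric$needs_envelope) {
      bids <- attr(part, "base_ids")
      if (is.null(cache) || is.null(bids))
        stop("envelope-based metrics need a partition cache", call. = FALSE)
      env <- hull_envelope_from_cache(cache, bids)
      if (is.null(env)) return(NA_real_)
    }
    metric$eval(part, env)
  }
  dfs <- function(start, ids, part) {
    for (i in start:nc) {
      p2 <- if (length(ids) == 0L) singles[[i]]
            else intersect_partitions(part, singles[[i]])
      ids2 <- c(ids, i)
      rows[[length(rows) + 1L]] <<-
        data.frame(size = length(ids2),
                   times = paste(nms[ids2], collapse = ","),
                   value = eval_subset(ids2, p2))
      if (length(ids2) < k_c && i < nc) dfs(i + 1L, ids2, p2)
    }
  }
  dfs(1L, integer(0), NULL)
  tab <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(seq_len(k_c), function(m) {
    sub <- tab[tab$size == m & !is.na(tab$value), , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(size = m, times = NA_character_, value = NA_real_))
    sub[which.min(sub$value), , drop = FALSE]
  }))
  rownames(best) <- NULL
  attr(best, "metric") <- metric$id
  if (all_subsets) attr(best, "table") <- tab
  best
}
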
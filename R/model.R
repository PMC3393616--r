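# ODE model definitions.

#' Define an ODE model for set-membership estimation
#'
#' The right-hand side is supplied as one R expression per state built from
#' the elementary operations `+`, `-`, `*`, `/` and integer powers, over the
#' state and parameter names.  Expressions are compiled once into an
#' elementary-operation tape from which validated Taylor coefficients of the
#' solution are generated; an unsupported operation is reported by name at
#' construction time.
#'
#' Models whose kinetics factor as `x_i' = x_i * g_i(x, p)` may declare the
#' per-capita rates `g_i` via `growth_rates` and assert `positive_states`.
#' Both are used (only when [enclosure_settings()] enables certificates) to
#' justify sound early discards of parameter boxes whose trajectories
#' provably escape the measurement corridor; see the package vignette.
#'
#' @param states Character vector of state names (dimension `n`).
#' @param params Character vector of parameter names (dimension `p`).
#' @param rhs Named list of expressions (`quote(...)`), one per state.
#' @param observed Integer indices of measured states.
#' @param growth_rates Optional named list of per-capita rate expressions.
#' @param positive_states Logical: are all states invariant in `[0, Inf)`
#'   for nonnegative initial conditions?  Only assert this when it follows
#'   from the model structure (e.g. every `rhs[[i]]` has factor `x_i`).
#' @param name Optional model name.
#' @return An object of class `"ode_model"`.
#' @examples
#' lotka_volterra_model()
#' @export
ode_model <- function(states, params, rhs, observed = seq_along(states),
                      growth_rates = NULL, positive_states = FALSE,
                      name = "model") {
  stopifnot(is.character(states), is.character(params), is.list(rhs))
  if (length(rhs) != length(states))
    stop("need one rhs expression per state", call. = FALSE)
  if (!is.null(names(rhs)) && !identical(names(rhs), states))
    rhs <- rhs[states]
  observed <- as.integer(observed)
  if (any(observed < 1L) || any(observed > length(states)))
    stop("observed indices outside 1..n", call. = FALSE)
  tape <- compile_tape(rhs, states, params)
  gtape <- NULL
  if (!is.null(growth_rates)) {
    if (!setequal(names(growth_rates), states))
      stop("growth_rates must name every state (or be NULL)", call. = FALSE)
    gtape <- compile_tape(growth_rates[states], states, params)
  }
  structure(list(states = states, params = params, rhs = rhs,
                 observed = observed, growth_rates = growth_rates,
                 positive_states = isTRUE(positive_states), name = name,
                 tape = tape, gtape = gtape,
                 n = length(states), p = length(params)),
            class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf("ode_model '%s': %d states, %d parameters\n", x$name, x$n, x$p))
  for (i in seq_len(x$n))
    cat(sprintf("  d%s/dt = %s\n", x$states[i], deparse(x$rhs[[i]])))
  cat("  observed:", paste(x$states[x$observed], collapse = ", "), "\n")
  invisible(x)
}

#' Lotka-Volterra predator-prey model
#'
#' Two-state predator-prey model `x1' = x1 (p1 - p2 x2)`,
#' `x2' = -x2 (p3 - p4 x1)` with prey `x1` (measured) and predator `x2`
#' (unmeasured): `p1` prey birth rate, `p2` predation loss rate, `p3`
#' predator death rate, `p4` predation gain rate.  The kinetics are in
#' factored per-capita form, so the growth rates are declared and the
#' positive orthant is invariant.
#'
#' @return An `"ode_model"`.
#' @export
lotka_volterra_model <- function() {
  ode_model(
    states = c("x1", "x2"),
    params = c("p1", "p2", "p3", "p4"),
    rhs = list(x1 = quote(x1 * (p1 - p2 * x2)),
               x2 = quote(-x2 * (p3 - p4 * x1))),
    observed = 1L,
    growth_rates = list(x1 = quote(p1 - p2 * x2),
                        x2 = quote(-(p3 - p4 * x1))),
    positive_states = TRUE,
    name = "lotka_volterra")
}

#' One-state exponential decay model
#'
#' `x' = -theta x`; closed form `x(t) = x0 exp(-theta t)` makes this the
#' standard toy for oracle tests of the estimation machinery.
#'
#' @return An `"ode_model"`.
#' @export
decay_model <- function() {
  ode_model(
    states = "x",
    params = "theta",
    rhs = list(x = quote(-theta * x)),
    observed = 1L,
    growth_rates = list(x = quote(-theta)),
    positive_states = TRUE,
    name = "decay")
}

#' Look up a packaged model by name
#' @param name One of `"lotka_volterra"`, `"decay"`.
#' @return An `"ode_model"`.
#' @export
get_model <- function(name) {
  switch(name,
         lotka_volterra = lotka_volterra_model(),
         decay = decay_model(),
         stop("unknown model '", name, "'", call. = FALSE))
}

# augmented box (states + params) as an n_in x 2 matrix for the C++ kernels
aug_matrix <- function(model, x, theta) {
  stopifnot(length(x$lo) == model$n, length(theta$lo) == model$p)
  cbind(c(x$lo, theta$lo), c(x$hi, theta$hi))
}

# point rhs closure for deSolve-based reference computations
model_derivs <- function(model) {
  n <- model$n
  function(t, y, parms) {
    env <- as.list(c(stats::setNames(y, model$states), parms))
    list(vapply(model$rhs, function(e) eval(e, env), numeric(1)))
  }
}
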
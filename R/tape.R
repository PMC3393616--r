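# Compilation of R expressions into elementary-operation tapes.
#
# A tape is the register-machine form of a model right-hand side consumed by
# the compiled Taylor-coefficient generator: registers 0..(n_in-1) hold the
# augmented state (states, then parameters), constants get dedicated
# registers, and every instruction is one of +, -, *, / or unary negation.
# Integer powers are expanded into repeated multiplication at compile time.

OP_ADD <- 1L; OP_SUB <- 2L; OP_MUL <- 3L; OP_DIV <- 4L; OP_NEG <- 5L

compile_tape <- function(exprs, states, params) {
  inputs <- c(states, params)
  n_in <- length(inputs)
  slot_of <- stats::setNames(seq_along(inputs) - 1L, inputs)
  consts <- numeric(0)
  const_slot <- integer(0)
  op <- integer(0); a1 <- integer(0); a2 <- integer(0); out <- integer(0)
  next_slot <- n_in

  new_slot <- function() {
    s <- next_slot
    next_slot <<- next_slot + 1L
    s
  }
  const_reg <- function(v) {
    hit <- which(consts == v)
    if (length(hit)) return(const_slot[hit[1L]])
    s <- new_slot()
    consts <<- c(consts, v)
    const_slot <<- c(const_slot, s)
    s
  }
  emit <- function(o, x, y) {
    force(o); force(x); force(y)  # operand recursion must run before slot allocation
    s <- new_slot()
    op <<- c(op, o); a1 <<- c(a1, x); a2 <<- c(a2, y); out <<- c(out, s)
    s
  }
  rec <- function(e) {
    if (is.numeric(e) && length(e) == 1L) return(const_reg(as.double(e)))
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (!nm %in% inputs)
        stop("unknown symbol in model expression: '", nm, "'", call. = FALSE)
      return(slot_of[[nm]])
    }
    if (!is.call(e))
      stop("unsupported expression node: ", deparse(e), call. = FALSE)
    fn <- as.character(e[[1L]])
    if (fn == "(") return(rec(e[[2L]]))
    if (fn == "-" && length(e) == 2L) {
      xa <- rec(e[[2L]])
      return(emit(OP_NEG, xa, 0L))
    }
    if (fn == "+" && length(e) == 2L) return(rec(e[[2L]]))
    if (fn == "^") {
      k <- e[[3L]]
      if (!is.numeric(k) || length(k) != 1L || k != round(k))
        stop("only integer powers are supported: ", deparse(e), call. = FALSE)
      k <- as.integer(k)
      if (k == 0L) return(const_reg(1))
      base <- rec(e[[2L]])
      neg <- k < 0L
      k <- abs(k)
      res <- base
      if (k > 1L) for (i in 2:k) res <- emit(OP_MUL, res, base)
      if (neg) {
        one <- const_reg(1)
        res <- emit(OP_DIV, one, res)
      }
      return(res)
    }
    if (fn %in% c("+", "-", "*", "/")) {
      x <- rec(e[[2L]]); y <- rec(e[[3L]])
      o <- switch(fn, "+" = OP_ADD, "-" = OP_SUB, "*" = OP_MUL, "/" = OP_DIV)
      return(emit(o, x, y))
    }
    stop("unsupported operation in model expression: '", fn, "'",
         call. = FALSE)
  }

  out_slot <- vapply(exprs, rec, integer(1))
  list(n_reg = next_slot, n_in = n_in, op = op, arg1 = a1, arg2 = a2,
       out = out, const_slot = const_slot, const_val = consts,
       out_slot = as.integer(out_slot))
}
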
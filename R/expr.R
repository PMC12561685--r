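# Expression-level utilities shared by the symbolic and numeric engines.

#' Parse a model expression string
#'
#' Model expressions use the grammar `+ - * / ^ ( )` with the functions
#' `exp`, `log`, `sqrt` and `tanh` over named symbols.
#'
#' @param s a character scalar.
#' @return an unevaluated R expression.
#' @keywords internal
parse_expr <- function(s) {
  ex <- tryCatch(str2lang(s), error = function(e) {
    stop("cannot parse expression: ", s, call. = FALSE)
  })
  check_expr_grammar(ex, s)
  ex
}

check_expr_grammar <- function(ex, src) {
  if (is.numeric(ex) || is.name(ex)) return(invisible(TRUE))
  if (!is.call(ex)) stop("unsupported component in expression: ", src, call. = FALSE)
  op <- as.character(ex[[1L]])
  allowed <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt", "tanh")
  if (!op %in% allowed) {
    stop("unsupported function '", op, "' in expression: ", src, call. = FALSE)
  }
  for (a in as.list(ex)[-1L]) check_expr_grammar(a, src)
  invisible(TRUE)
}

# Rewrite to a differentiation-friendly normal form:
#   a^b (b not an integer literal) -> exp(b * log(a))
#   tanh(z) -> (exp(2z) - 1) / (exp(2z) + 1)
#   sqrt(a) -> exp(0.5 * log(a))
# The single-exp/log forms keep transcendental subterms canonical, which the
# exact-rank evaluation relies on (each distinct transcendental value is
# treated as one independent generic quantity).
rewrite_expr <- function(ex) {
  if (is.numeric(ex) || is.name(ex)) return(ex)
  ex <- as.call(c(ex[[1L]], lapply(as.list(ex)[-1L], rewrite_expr)))
  op <- as.character(ex[[1L]])
  if (op == "^" && !(is.numeric(ex[[3L]]) && ex[[3L]] == round(ex[[3L]]))) {
    return(call("exp", call("*", ex[[3L]], call("log", ex[[2L]]))))
  }
  if (op == "tanh") {
    E <- call("exp", call("*", 2, ex[[2L]]))
    return(call("/", call("-", E, 1), call("+", E, 1)))
  }
  if (op == "sqrt") return(call("exp", call("*", 0.5, call("log", ex[[2L]]))))
  ex
}

expr_symbols <- function(ex) all.vars(ex)

expr_nodes <- function(ex) {
  if (!is.call(ex)) return(1L)
  1L + sum(vapply(as.list(ex)[-1L], expr_nodes, integer(1)))
}

# A minimal evaluation environment: arithmetic plus the supported functions,
# nothing else, so an unbound symbol errors instead of picking up base R
# objects such as T or C.
math_env <- local({
  e <- new.env(parent = emptyenv())
  for (f in c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt", "tanh", "c",
              "list")) {
    assign(f, get(f, baseenv()), envir = e)
  }
  e
})

#' Evaluate an expression at a named point
#'
#' Division by (numerical) zero and other non-finite results are flagged by
#' returning `NA_real_` rather than erroring, so that samplers can reject the
#' point.
#' @keywords internal
eval_expr <- function(ex, values) {
  env <- list2env(as.list(values), parent = math_env)
  v <- tryCatch(eval(ex, env), error = function(e) NA_real_)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) return(NA_real_)
  v
}
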
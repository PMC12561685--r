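#' Define an ODE model for structural identifiability analysis
#'
#' A model is the tuple \eqn{\dot x = f(u, x, \theta)}, \eqn{y = h(u, x, \theta)}:
#' named states, unknown constant parameters, known treatment inputs, and
#' candidate output expressions. Initial conditions of all states are treated
#' as unknown quantities to be inferred, matching the augmented-state
#' formulation in which states and parameters are analysed jointly.
#'
#' @param acronym short identifier, e.g. `"LOG"`.
#' @param states character vector of state names (declaration order is the
#'   canonical column order of all matrices).
#' @param params character vector of unknown parameter names.
#' @param dynamics named character vector mapping each state to the expression
#'   string of its time derivative. Expressions use `+ - * / ^ ( )`, `exp`,
#'   `log`, `sqrt`, `tanh`.
#' @param outputs named character vector of candidate output expressions.
#' @param inputs known (treatment) inputs: a named integer vector mapping each
#'   input name to its number of nonzero time derivatives (0 = constant input).
#'   A value `q > 0` means the input is a known smooth function whose
#'   derivatives up to order `q` are nonzero; simulation realises it as the
#'   polynomial \eqn{u(t) = \sum_{j\le q} u^{(j)}(0)\, t^j/j!}.
#' @param known_constants named numeric vector of known constants, substituted
#'   into the expressions.
#' @param unit_symbols symbols (states or parameters) that live on the unit
#'   interval, e.g. population fractions or exponents with \eqn{0<\gamma<1};
#'   generic points sample these in (0, 1).
#' @param horizon default time horizon (model time units) for simulation-based
#'   operations; chosen per model so trajectories stay finite and positive.
#' @param references free-text equation citations.
#'
#' @return an object of class `sio_model`.
#' @examples
#' m <- sio_model("LOG", states = "N", params = c("a", "K"),
#'                dynamics = c(N = "a*N*(1-N/K)"), outputs = c(N = "N"))
#' augmented_state(m)
#' @export
sio_model <- function(acronym, states, params, dynamics, outputs,
                      inputs = NULL, known_constants = NULL,
                      unit_symbols = character(0), horizon = 1,
                      references = character(0)) {
  states <- as.character(states)
  params <- as.character(params)
  if (anyDuplicated(c(states, params))) {
    stop("duplicate symbols among states/params", call. = FALSE)
  }
  if (length(dynamics) != length(states)) {
    stop("arity error: ", length(dynamics), " dynamics for ",
         length(states), " states", call. = FALSE)
  }
  if (is.null(names(dynamics))) names(dynamics) <- states
  if (!setequal(names(dynamics), states)) {
    stop("dynamics must be named by state", call. = FALSE)
  }
  dynamics <- dynamics[states]
  if (length(outputs) == 0L) stop("at least one candidate output is required", call. = FALSE)
  if (is.null(names(outputs))) names(outputs) <- as.character(outputs)

  if (is.null(inputs)) inputs <- integer(0)
  input_names <- names(inputs)
  inq <- as.integer(inputs)
  names(inq) <- input_names
  if (any(inq < 0)) stop("nonzero_derivatives must be >= 0", call. = FALSE)

  kc <- if (is.null(known_constants)) numeric(0) else known_constants

  dyn_ex <- lapply(dynamics, parse_expr)
  out_ex <- lapply(outputs, parse_expr)

  known <- c(states, params, input_names, names(kc))
  for (nm in names(dyn_ex)) {
    bad <- setdiff(expr_symbols(dyn_ex[[nm]]), known)
    if (length(bad)) {
      stop("unknown symbol '", bad[1L], "' in dynamics of ", nm, call. = FALSE)
    }
  }
  for (nm in names(out_ex)) {
    bad <- setdiff(expr_symbols(out_ex[[nm]]), known)
    if (length(bad)) {
      stop("unknown symbol '", bad[1L], "' in output ", nm, call. = FALSE)
    }
  }
  bad_unit <- setdiff(unit_symbols, c(states, params))
  if (length(bad_unit)) stop("unknown unit symbol: ", bad_unit[1L], call. = FALSE)

  # substitute known constants, then keep both raw and rewritten forms
  subst <- function(ex) do.call(substitute, list(ex, as.list(kc)))
  dyn_s <- lapply(dyn_ex, subst)
  out_s <- lapply(out_ex, subst)

  structure(list(
    acronym = acronym,
    states = states,
    params = params,
    inputs = inq,
    known_constants = kc,
    dynamics_src = vapply(dynamics, as.character, ""),
    outputs_src = vapply(outputs, as.character, ""),
    dynamics = dyn_s,
    outputs = out_s,
    dynamics_rw = lapply(dyn_s, rewrite_expr),
    outputs_rw = lapply(out_s, rewrite_expr),
    unit_symbols = unit_symbols,
    horizon = horizon,
    references = references
  ), class = "sio_model")
}

#' @rdname sio_model
#' @param spec a list with the fields of [sio_model()] (as produced by
#'   [read_model()]).
#' @export
make_model <- function(spec) {
  do.call(sio_model, spec)
}

#' Augmented state vector
#'
#' States followed by unknown parameters, in declaration order. This is the
#' canonical column order of every identifiability matrix.
#'
#' @param model an `sio_model`.
#' @return character vector of length `nx + ntheta`.
#' @export
augmented_state <- function(model) {
  stopifnot(inherits(model, "sio_model"))
  c(model$states, model$params)
}

# input derivative symbols u, u_d1, ..., u_dq appearing in Lie derivatives
input_symbols <- function(model) {
  unlist(lapply(names(model$inputs), function(u) {
    q <- model$inputs[[u]]
    c(u, if (q > 0) paste0(u, "_d", seq_len(q)))
  }), use.names = FALSE)
}

n_aug <- function(model) length(model$states) + length(model$params)

#' @export
print.sio_model <- function(x, ...) {
  cat(sprintf("<sio_model %s>  nx = %d, ntheta = %d\n", x$acronym,
              length(x$states), length(x$params)))
  cat("  states:  ", paste(x$states, collapse = ", "), "\n")
  cat("  params:  ", paste(x$params, collapse = ", "), "\n")
  if (length(x$inputs)) {
    cat("  inputs:  ", paste(sprintf("%s (%d nonzero derivs)", names(x$inputs),
                                     x$inputs), collapse = ", "), "\n")
  }
  for (s in x$states) cat(sprintf("  d%s/dt = %s\n", s, x$dynamics_src[[s]]))
  cat("  outputs: ",
      paste(sprintf("%s = %s", names(x$outputs_src), x$outputs_src), collapse = "; "),
      "\n")
  invisible(x)
}

#' Write / read a model definition file
#'
#' Models round-trip through a YAML file with keys `acronym, states, params,
#' known_constants, inputs, dynamics, outputs` (plus optional `unit_symbols`,
#' `horizon`, `references`).
#'
#' @param model an `sio_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  obj <- list(
    acronym = model$acronym,
    states = as.list(model$states),
    params = as.list(model$params),
    known_constants = as.list(model$known_constants),
    inputs = lapply(names(model$inputs), function(u) {
      list(name = u, nonzero_derivatives = unname(model$inputs[[u]]))
    }),
    dynamics = as.list(model$dynamics_src),
    outputs = as.list(model$outputs_src),
    unit_symbols = as.list(model$unit_symbols),
    horizon = model$horizon,
    references = as.list(model$references)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- yaml::read_yaml(path)
  inputs <- NULL
  if (length(obj$inputs)) {
    inputs <- stats::setNames(
      vapply(obj$inputs, function(i) as.integer(i$nonzero_derivatives), 0L),
      vapply(obj$inputs, function(i) i$name, ""))
  }
  sio_model(
    acronym = obj$acronym,
    states = unlist(obj$states),
    params = unlist(obj$params),
    dynamics = unlist(obj$dynamics),
    outputs = unlist(obj$outputs),
    inputs = inputs,
    known_constants = if (length(obj$known_constants)) unlist(obj$known_constants),
    unit_symbols = if (length(obj$unit_symbols)) unlist(obj$unit_symbols) else character(0),
    horizon = if (is.null(obj$horizon)) 1 else obj$horizon,
    references = if (length(obj$references)) unlist(obj$references) else character(0)
  )
}
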
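# Symbolic observability-identifiability (OI) matrix from Lie derivatives.
#
# The OI matrix stacks the Jacobians of successive Lie derivatives of the
# measured outputs with respect to the augmented state (states, then
# parameters), up to at most order nx + ntheta - 1. Entries are kept in the
# canonical sparse-polynomial form of poly.R, so repeated differentiation
# collapses instead of swelling.

# build the polynomial context for a (model, measured-outputs) pair
lie_context <- function(model, measured, term_budget = 5e5) {
  measured <- resolve_measured(model, measured)
  vars <- c(model$states, model$params, input_symbols(model))
  ctx <- new_poly_ctx(vars, term_budget = term_budget)
  f <- lapply(model$dynamics_rw, p_from_expr, ctx = ctx)
  h <- lapply(model$outputs_rw[measured], p_from_expr, ctx = ctx)
  list(ctx = ctx, f = f, h = h, measured = measured, model = model)
}

resolve_measured <- function(model, measured) {
  if (is.null(measured)) return(names(model$outputs))
  bad <- setdiff(measured, names(model$outputs))
  if (length(bad)) {
    stop("unknown output name '", bad[1L], "'; available: ",
         paste(names(model$outputs), collapse = ", "), call. = FALSE)
  }
  measured
}

# one Lie step: L_new = sum_j dL/dx_j f_j + sum_u sum_{r<q} dL/du^(r) u^(r+1)
lie_step <- function(L, lc) {
  ctx <- lc$ctx
  model <- lc$model
  acc <- p_zero(ctx)
  for (j in seq_along(model$states)) {
    d <- p_deriv(L, model$states[[j]], ctx)
    if (p_nterm(d) > 0L) acc <- p_add(acc, p_mul(d, lc$f[[j]], ctx), ctx)
  }
  for (u in names(model$inputs)) {
    q <- model$inputs[[u]]
    if (q == 0L) next
    dsyms <- c(u, paste0(u, "_d", seq_len(q)))
    for (r in seq_len(q)) { # term d(.)/du^(r-1) * u^(r)
      d <- p_deriv(L, dsyms[[r]], ctx)
      if (p_nterm(d) > 0L) {
        acc <- p_add(acc, p_mul(d, p_var(ctx, dsyms[[r + 1L]]), ctx), ctx)
      }
    }
  }
  acc
}

#' Lie derivatives of the measured outputs
#'
#' Order 0 returns the output expressions themselves; order `i` applies the
#' extended Lie derivative `i` times (directional derivative along the vector
#' field plus input-derivative terms, truncated at each input's declared
#' number of nonzero derivatives).
#'
#' @param model an `sio_model`.
#' @param measured character vector of output names (default: all).
#' @param order derivative order (>= 0).
#' @param term_budget per-entry budget on polynomial terms; exceeding it
#'   raises a condition of class `oncosio_swell`.
#' @return a named list of polynomial expressions (one per measured output);
#'   `format()` renders them as canonical strings.
#' @export
lie_derivative <- function(model, measured = NULL, order = 0L,
                           term_budget = 5e5) {
  lc <- lie_context(model, measured, term_budget)
  out <- lc$h
  for (k in seq_len(order)) out <- lapply(out, lie_step, lc = lc)
  for (nm in names(out)) attr(out[[nm]], "vars") <- lc$ctx$vars
  out
}

oi_gradient_rows <- function(L_list, lc) {
  aug <- augmented_state(lc$model)
  lapply(L_list, function(L) lapply(aug, function(s) p_deriv(L, s, lc$ctx)))
}

new_oi <- function(rows, order, lc) {
  structure(list(
    rows = rows,                      # list over orders of list over outputs of list over columns
    order = order,
    column_symbols = augmented_state(lc$model),
    measured = lc$measured,
    acronym = lc$model$acronym,
    lc = lc
  ), class = "sio_oi")
}

#' Build the observability-identifiability matrix
#'
#' Stacks the Jacobians of Lie derivative orders `0..max_order` of the
#' measured outputs, columns ordered by [augmented_state()].
#'
#' @inheritParams lie_derivative
#' @param max_order maximum Lie order; capped at `nx + ntheta - 1`.
#' @return an object of class `sio_oi`.
#' @export
build_oi <- function(model, measured = NULL, max_order = NULL,
                     term_budget = 5e5) {
  cap <- n_aug(model) - 1L
  if (is.null(max_order)) max_order <- cap
  if (max_order > cap) {
    stop("max_order exceeds the nx + ntheta - 1 cap (", cap, ")", call. = FALSE)
  }
  lc <- lie_context(model, measured, term_budget)
  rows <- vector("list", max_order + 1L)
  L <- lc$h
  rows[[1L]] <- oi_gradient_rows(L, lc)
  for (k in seq_len(max_order)) {
    L <- lapply(L, lie_step, lc = lc)
    rows[[k + 1L]] <- oi_gradient_rows(L, lc)
  }
  new_oi(rows, max_order, lc)
}

#' @export
print.sio_oi <- function(x, ...) {
  ny <- length(x$measured)
  cat(sprintf("<sio_oi %s | y = {%s}>  %d x %d (orders 0..%d)\n",
              x$acronym, paste(x$measured, collapse = ", "),
              (x$order + 1L) * ny, length(x$column_symbols), x$order))
  invisible(x)
}

#' Dump OI matrix entries as text
#'
#' One entry per line, row-major, in canonical polynomial form.
#' @param oi an `sio_oi`.
#' @param path optional file; if `NULL` the lines are returned.
#' @export
oi_dump <- function(oi, path = NULL) {
  vars <- oi$lc$ctx$vars
  lines <- character(0)
  for (blk in oi$rows) for (out_row in blk) {
    lines <- c(lines, vapply(out_row, format, "", vars = vars))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

# evaluate the aux symbols of a poly context over GF(p).
# Inverse aux get honest modular inverses of their defining polynomial value;
# exp/log/tanh aux are transcendental over the rational function field and
# receive independent random field elements. Returns NULL on a pole.
ctx_values_modp <- function(ctx, base_values) {
  vals <- rep(NA_real_, ctx_nv(ctx))
  names(vals) <- ctx$vars
  vals[names(base_values)] <- base_values
  for (nm in names(ctx$aux)) {
    a <- ctx$aux[[nm]]
    if (a$op == "inv") {
      q <- p_eval_modp(a$def, vals)
      if (q == 0) return(NULL)
      vals[[nm]] <- mod_inv(q)
    } else {
      vals[[nm]] <- sample(2:(MOD_P - 2), 1L)
    }
  }
  vals
}

p_eval_modp <- function(p, vals) {
  n <- p_nterm(p)
  if (n == 0L) return(0)
  m <- rep(1, n)
  for (j in seq_len(ncol(p$e))) {
    ej <- p$e[, j]
    nz <- which(ej != 0L)
    if (length(nz)) {
      vpow <- vapply(unique(ej[nz]), function(k) mod_pow(vals[[j]], k), 0)
      names(vpow) <- as.character(unique(ej[nz]))
      m[nz] <- mod_mul(m[nz], vpow[as.character(ej[nz])])
    }
  }
  co <- vapply(p$c, mod_rational, 0)
  sum(mod_mul(co, m)) %% MOD_P
}

# numeric (field) evaluation of the OI matrix at one seeded point
oi_eval_modp <- function(oi, seed) {
  model <- oi$lc$model
  base <- field_point(model, seed)
  vals <- with_seed(seed + 7L, ctx_values_modp(oi$lc$ctx, base))
  if (is.null(vals)) return(NULL)
  rows <- list()
  for (blk in oi$rows) for (out_row in blk) {
    rows[[length(rows) + 1L]] <- vapply(out_row, p_eval_modp, 0, vals = vals)
  }
  M <- do.call(rbind, rows)
  colnames(M) <- oi$column_symbols
  M
}

# float evaluation at a named numeric point (for inspection / cross-checks)
oi_eval <- function(oi, point) {
  vals <- ctx_values(oi$lc$ctx, c(point, oi$lc$model$known_constants))
  if (is.null(vals)) stop("pole at evaluation point", call. = FALSE)
  rows <- list()
  for (blk in oi$rows) for (out_row in blk) {
    rows[[length(rows) + 1L]] <- vapply(out_row, p_eval, 0, vals = vals)
  }
  M <- do.call(rbind, rows)
  colnames(M) <- oi$column_symbols
  M
}

#' Generic rank of an OI matrix
#'
#' Evaluates the matrix at `trials` independent generic points over a prime
#' field and returns the maximum exact rank observed (the rank at a generic
#' point equals the structural rank with probability 1).
#'
#' @param oi an `sio_oi`.
#' @param seed integer seed.
#' @param trials number of evaluation points (>= 1).
#' @export
generic_rank <- function(oi, seed = 1L, trials = 3L) {
  stopifnot(trials >= 1L)
  r <- 0L
  ok <- FALSE
  for (i in seq_len(trials)) {
    M <- oi_eval_modp(oi, seed + (i - 1L) * 101L)
    if (is.null(M)) next
    ok <- TRUE
    r <- max(r, rank_modp(M))
  }
  if (!ok) stop("sampling failure: all evaluation points rejected (poles)",
                call. = FALSE)
  r
}

#' Saturated OI matrix with early stop
#'
#' Grows the matrix one Lie order at a time, recomputing the generic rank,
#' and stops as soon as the rank is unchanged by one additional order, or
#' full rank `nx + ntheta` is reached, or the order cap applies. Once the
#' observability filtration stalls it stays stalled, so the returned matrix
#' has the same generic rank as the cap-order matrix.
#'
#' @inheritParams build_oi
#' @param seed,trials rank evaluation controls, as in [generic_rank()].
#' @return an `sio_oi` with attributes `rank` and `ranks` (per-order).
#' @export
saturated_oi <- function(model, measured = NULL, seed = 1L, trials = 3L,
                         term_budget = 5e5) {
  cap <- n_aug(model) - 1L
  naug <- n_aug(model)
  lc <- lie_context(model, measured, term_budget)
  base_pts <- list()
  aux_seeds <- integer(0)
  for (i in seq_len(trials)) {
    base_pts[[i]] <- field_point(model, seed + (i - 1L) * 101L)
    aux_seeds[i] <- seed + (i - 1L) * 101L + 7L
  }
  eval_rows <- rep(list(NULL), trials) # accumulated numeric rows per trial
  rows <- list()
  ranks <- integer(0)
  L <- lc$h
  prev_rank <- -1L
  for (k in 0:cap) {
    if (k > 0L) L <- lapply(L, lie_step, lc = lc)
    grad <- oi_gradient_rows(L, lc)
    rows[[k + 1L]] <- grad
    rk <- 0L
    for (i in seq_len(trials)) {
      vals <- with_seed(aux_seeds[i], ctx_values_modp(lc$ctx, base_pts[[i]]))
      if (is.null(vals)) next
      newrows <- do.call(rbind, lapply(grad, function(g) {
        vapply(g, p_eval_modp, 0, vals = vals)
      }))
      eval_rows[[i]] <- rbind(eval_rows[[i]], newrows)
      rk <- max(rk, rank_modp(eval_rows[[i]]))
    }
    ranks[k + 1L] <- rk
    if (rk == naug || rk == prev_rank) break
    prev_rank <- rk
  }
  oi <- new_oi(rows, length(rows) - 1L, lc)
  attr(oi, "rank") <- ranks[length(ranks)]
  attr(oi, "ranks") <- ranks
  attr(oi, "eval_rows") <- eval_rows
  attr(oi, "seed") <- seed
  oi
}
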
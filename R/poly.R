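# Sparse multivariate polynomial arithmetic with auxiliary symbols.
#
# Lie derivatives of rational/analytic vector fields swell exponentially as raw
# expression trees. Here every expression is kept in collapsed canonical form:
# a sparse polynomial over the model symbols plus auxiliary symbols that stand
# for 1/e, exp(e), log(e) and tanh(e) subterms. Each auxiliary symbol carries a
# chain-rule partial that is itself polynomial in the extended symbol set, so
# differentiation is closed and never expands quotients or transcendentals.

new_poly_ctx <- function(vars, term_budget = 2e5) {
  ctx <- new.env(parent = emptyenv())
  ctx$vars <- as.character(vars)
  ctx$aux <- list()          # name -> list(op, def = spoly, key)
  ctx$aux_keys <- character() # key -> aux name (named chr)
  ctx$partials <- new.env(parent = emptyenv()) # "aux|sym" -> spoly
  ctx$term_budget <- term_budget
  ctx
}

ctx_nv <- function(ctx) length(ctx$vars)

p_zero <- function(ctx) {
  structure(list(e = matrix(0L, 0L, ctx_nv(ctx)), c = numeric(0)), class = "spoly")
}

p_const <- function(ctx, k) {
  if (k == 0) return(p_zero(ctx))
  structure(list(e = matrix(0L, 1L, ctx_nv(ctx)), c = as.numeric(k)), class = "spoly")
}

p_var <- function(ctx, name) {
  i <- match(name, ctx$vars)
  if (is.na(i)) stop("unknown symbol in polynomial context: ", name)
  e <- matrix(0L, 1L, ctx_nv(ctx))
  e[1L, i] <- 1L
  structure(list(e = e, c = 1), class = "spoly")
}

p_nterm <- function(p) length(p$c)

p_pad <- function(p, nv) {
  k <- nv - ncol(p$e)
  if (k <= 0L) return(p)
  p$e <- cbind(p$e, matrix(0L, nrow(p$e), k))
  p
}

p_collapse <- function(e, c, budget = Inf) {
  if (length(c) == 0L) return(list(e = e, c = c))
  key <- do.call(paste, c(lapply(seq_len(ncol(e)), function(j) e[, j]), sep = ","))
  if (anyDuplicated(key)) {
    c <- as.vector(rowsum(c, key, reorder = FALSE))
    e <- e[!duplicated(key), , drop = FALSE]
  }
  keep <- c != 0
  e <- e[keep, , drop = FALSE]
  c <- c[keep]
  if (length(c) > budget) {
    stop(structure(class = c("oncosio_swell", "error", "condition"),
                   list(message = sprintf("expression exceeded term budget (%d terms)", length(c)),
                        call = NULL)))
  }
  list(e = e, c = c)
}

p_canon <- function(p, ctx) {
  r <- p_collapse(p$e, p$c, ctx$term_budget)
  structure(r, class = "spoly")
}

p_add <- function(a, b, ctx) {
  force(a); force(b) # promises may create aux symbols, enlarging the context
  nv <- ctx_nv(ctx)
  a <- p_pad(a, nv); b <- p_pad(b, nv)
  p_canon(structure(list(e = rbind(a$e, b$e), c = c(a$c, b$c)), class = "spoly"), ctx)
}

p_scale <- function(a, k, ctx) {
  if (k == 0) return(p_zero(ctx))
  a$c <- a$c * k
  a
}

p_sub <- function(a, b, ctx) p_add(a, p_scale(b, -1, ctx), ctx)

p_mul <- function(a, b, ctx) {
  force(a); force(b)
  nv <- ctx_nv(ctx)
  a <- p_pad(a, nv); b <- p_pad(b, nv)
  na <- p_nterm(a); nb <- p_nterm(b)
  if (na == 0L || nb == 0L) return(p_zero(ctx))
  if (na * nb > 8 * ctx$term_budget) {
    stop(structure(class = c("oncosio_swell", "error", "condition"),
                   list(message = "product exceeds term budget", call = NULL)))
  }
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  e <- a$e[ia, , drop = FALSE] + b$e[ib, , drop = FALSE]
  p_canon(structure(list(e = e, c = a$c[ia] * b$c[ib]), class = "spoly"), ctx)
}

p_pow_int <- function(a, n, ctx) {
  n <- as.integer(n)
  if (n == 0L) return(p_const(ctx, 1))
  out <- a
  for (i in seq_len(n - 1L)) out <- p_mul(out, a, ctx)
  out
}

p_is_const <- function(p) {
  p_nterm(p) == 0L || (p_nterm(p) == 1L && all(p$e == 0L))
}

p_const_value <- function(p) if (p_nterm(p) == 0L) 0 else p$c[[1L]]

poly_key <- function(p) {
  if (p_nterm(p) == 0L) return("0")
  o <- order(do.call(paste, c(lapply(seq_len(ncol(p$e)), function(j) sprintf("%05d", p$e[, j])), sep = ",")))
  paste(apply(p$e[o, , drop = FALSE], 1L, paste, collapse = ","), signif(p$c[o], 12),
        sep = ":", collapse = ";")
}

# -- auxiliary symbols ---------------------------------------------------------

aux_new <- function(ctx, op, def) {
  key <- paste0(op, "|", poly_key(def), "|", ncol(def$e))
  hit <- ctx$aux_keys[key]
  if (!is.na(hit)) return(unname(hit))
  nm <- sprintf(".z%d", length(ctx$aux) + 1L)
  ctx$vars <- c(ctx$vars, nm)
  ctx$aux[[nm]] <- list(op = op, def = def, key = key)
  ctx$aux_keys[key] <- nm
  nm
}

p_inv <- function(a, ctx) {
  if (p_is_const(a)) {
    v <- p_const_value(a)
    if (v == 0) stop("division by zero in model expression")
    return(p_const(ctx, 1 / v))
  }
  # 1/x for a bare symbol x reuses a single aux; general expressions dedup by key
  p_var(ctx, aux_new(ctx, "inv", a))
}

p_exp <- function(a, ctx) {
  if (p_is_const(a)) return(p_const(ctx, exp(p_const_value(a))))
  p_var(ctx, aux_new(ctx, "exp", a))
}

p_log <- function(a, ctx) {
  if (p_is_const(a)) return(p_const(ctx, log(p_const_value(a))))
  p_var(ctx, aux_new(ctx, "log", a))
}

p_tanh <- function(a, ctx) {
  if (p_is_const(a)) return(p_const(ctx, tanh(p_const_value(a))))
  p_var(ctx, aux_new(ctx, "tanh", a))
}

# total derivative d(aux)/d(sym), memoised
aux_partial <- function(ctx, aux_name, sym) {
  key <- paste0(aux_name, "|", sym)
  hit <- ctx$partials[[key]]
  if (!is.null(hit)) return(hit)
  a <- ctx$aux[[aux_name]]
  dq <- p_deriv(a$def, sym, ctx)
  av <- p_var(ctx, aux_name)
  res <- switch(a$op,
    inv  = p_scale(p_mul(p_mul(av, av, ctx), dq, ctx), -1, ctx),
    exp  = p_mul(av, dq, ctx),
    log  = p_mul(p_inv(a$def, ctx), dq, ctx),
    tanh = p_mul(p_sub(p_const(ctx, 1), p_mul(av, av, ctx), ctx), dq, ctx),
    stop("unknown aux op: ", a$op)
  )
  ctx$partials[[key]] <- res
  res
}

# total derivative of p w.r.t. base symbol sym (chain rule through aux symbols)
p_deriv <- function(p, sym, ctx) {
  nv <- ctx_nv(ctx)
  p <- p_pad(p, nv)
  if (p_nterm(p) == 0L) return(p_zero(ctx))
  out <- p_zero(ctx)
  present <- which(colSums(p$e != 0L) > 0L)
  for (j in present) {
    v <- ctx$vars[[j]]
    rows <- p$e[, j] > 0L
    e <- p$e[rows, , drop = FALSE]
    cc <- p$c[rows] * e[, j]
    e[, j] <- e[, j] - 1L
    pj <- structure(list(e = e, c = cc), class = "spoly")
    if (v == sym) {
      out <- p_add(out, pj, ctx)
    } else if (!is.null(ctx$aux[[v]])) {
      dv <- aux_partial(ctx, v, sym)
      if (p_nterm(dv) > 0L) out <- p_add(out, p_mul(pj, dv, ctx), ctx)
    } # base symbol != sym contributes nothing
  }
  out
}

# -- building polynomials from R expressions ----------------------------------

p_from_expr <- function(ex, ctx) {
  if (is.numeric(ex)) return(p_const(ctx, ex))
  if (is.name(ex)) return(p_var(ctx, as.character(ex)))
  if (!is.call(ex)) stop("unsupported expression component: ", deparse(ex))
  op <- as.character(ex[[1L]])
  if (op == "(") return(p_from_expr(ex[[2L]], ctx))
  if (op == "+" && length(ex) == 2L) return(p_from_expr(ex[[2L]], ctx))
  if (op == "-" && length(ex) == 2L) return(p_scale(p_from_expr(ex[[2L]], ctx), -1, ctx))
  a <- p_from_expr(ex[[2L]], ctx)
  switch(op,
    "+" = p_add(a, p_from_expr(ex[[3L]], ctx), ctx),
    "-" = p_sub(a, p_from_expr(ex[[3L]], ctx), ctx),
    "*" = p_mul(a, p_from_expr(ex[[3L]], ctx), ctx),
    "/" = p_mul(a, p_inv(p_from_expr(ex[[3L]], ctx), ctx), ctx),
    "^" = {
      b <- ex[[3L]]
      if (is.numeric(b) && b == round(b)) {
        if (b >= 0) p_pow_int(a, b, ctx) else p_inv(p_pow_int(a, -b, ctx), ctx)
      } else {
        p_exp(p_mul(p_from_expr(b, ctx), p_log(a, ctx), ctx), ctx)
      }
    },
    "exp"  = p_exp(a, ctx),
    "log"  = p_log(a, ctx),
    "sqrt" = p_exp(p_scale(p_log(a, ctx), 0.5, ctx), ctx),
    "tanh" = p_tanh(a, ctx),
    stop("unsupported function in model expression: ", op)
  )
}

# -- evaluation ---------------------------------------------------------------

# values: named numeric over base symbols; aux symbols are computed in creation
# order (definitions only reference earlier symbols).
ctx_values <- function(ctx, base_values) {
  vals <- rep(NA_real_, ctx_nv(ctx))
  names(vals) <- ctx$vars
  vals[names(base_values)] <- base_values
  for (nm in names(ctx$aux)) {
    a <- ctx$aux[[nm]]
    q <- p_eval(a$def, vals)
    vals[[nm]] <- switch(a$op,
      inv = { if (abs(q) < 1e-9) return(NULL); 1 / q },
      exp = exp(q), log = { if (q <= 0) return(NULL); log(q) }, tanh = tanh(q))
    if (!is.finite(vals[[nm]])) return(NULL)
  }
  vals
}

p_eval <- function(p, vals) {
  n <- p_nterm(p)
  if (n == 0L) return(0)
  m <- rep(1, n)
  for (j in seq_len(ncol(p$e))) {
    ej <- p$e[, j]
    nz <- ej != 0L
    if (any(nz)) m[nz] <- m[nz] * vals[[j]]^ej[nz]
  }
  sum(p$c * m)
}

#' @export
format.spoly <- function(x, ..., vars = NULL) {
  if (p_nterm(x) == 0L) return("0")
  if (is.null(vars)) vars <- paste0("v", seq_len(ncol(x$e)))
  terms <- vapply(seq_along(x$c), function(i) {
    e <- x$e[i, ]
    facs <- character(0)
    for (j in which(e != 0L)) {
      facs <- c(facs, if (e[j] == 1L) vars[[j]] else paste0(vars[[j]], "^", e[j]))
    }
    co <- x$c[[i]]
    if (length(facs) == 0L) return(format(co))
    body <- paste(facs, collapse = "*")
    if (co == 1) body else if (co == -1) paste0("-", body) else paste0(format(co), "*", body)
  }, character(1))
  # canonical order for stable output
  paste(terms[order(terms)], collapse = " + ")
}

#' @export
print.spoly <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}
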
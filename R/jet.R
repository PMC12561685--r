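# Numeric OI matrix via Taylor expansion of the forward sensitivity system.
#
# For models too large for symbolic Lie calculus, the same matrix is obtained
# numerically: propagate truncated Taylor series (jets) of the state together
# with the forward variational equations dS/dt = (df/dx) S + [0 | df/dtheta],
# S(0) = [I | 0]; the k-th Taylor coefficient of (dh/dx) S + [0 | dh/dtheta]
# is, up to the factor k!, the Jacobian of the k-th Lie derivative of the
# output, i.e. the k-th row block of the OI matrix evaluated at the point.
# Rank decisions run the whole recursion exactly over GF(p).

# ---- truncated power series over GF(p) --------------------------------------
# a series is a numeric vector of field elements, orders 0..N

sm_mul <- function(a, b) {
  n <- length(a)
  out <- numeric(n)
  for (k in seq_len(n)) out[k] <- sum(mod_mul(a[1:k], b[k:1])) %% MOD_P
  out
}
sm_div <- function(a, b) {
  n <- length(a)
  if (b[1L] == 0) stop(pole_condition())
  out <- numeric(n)
  ib <- mod_inv(b[1L])
  out[1L] <- mod_mul(a[1L], ib)
  for (k in seq_len(n)[-1L]) {
    out[k] <- mod_mul((a[k] - sum(mod_mul(b[2:k], out[(k - 1):1]))) %% MOD_P, ib)
  }
  out
}
sm_exp <- function(a, lead) {
  n <- length(a)
  out <- numeric(n)
  out[1L] <- lead("exp", a[1L])
  for (k in seq_len(n)[-1L]) {
    i <- 1:(k - 1)
    s <- sum(mod_mul((k - i) %% MOD_P, mod_mul(a[k - i + 1], out[i]))) %% MOD_P
    out[k] <- mod_mul(s, mod_inv((k - 1) %% MOD_P))
  }
  out
}
sm_log <- function(a, lead) {
  n <- length(a)
  if (a[1L] == 0) stop(pole_condition())
  out <- numeric(n)
  out[1L] <- lead("log", a[1L])
  ia <- mod_inv(a[1L])
  for (k in seq_len(n)[-1L]) {
    s <- 0
    if (k > 2L) {
      i <- 1:(k - 2)
      s <- mod_mul(sum(mod_mul(i %% MOD_P, mod_mul(out[i + 1L], a[k - i]))) %% MOD_P,
                   mod_inv((k - 1) %% MOD_P))
    }
    out[k] <- mod_mul((a[k] - s) %% MOD_P, ia)
  }
  out
}
sm_tanh <- function(a, lead) {
  n <- length(a)
  g <- numeric(n)
  g[1L] <- lead("tanh", a[1L])
  for (k in seq_len(n)[-1L]) {
    w <- (MOD_P - sm_mul(g, g)) %% MOD_P
    w[1L] <- (w[1L] + 1) %% MOD_P
    i <- 1:(k - 1)
    s <- sum(mod_mul(i %% MOD_P, mod_mul(a[i + 1L], w[k - i]))) %% MOD_P
    g[k] <- mod_mul(s, mod_inv((k - 1) %% MOD_P))
  }
  g
}

sm_eval <- function(ex, env, N, lead) {
  if (is.numeric(ex)) {
    out <- c(mod_rational(ex), numeric(N))
    if (ex == round(ex) && ex >= 0 && ex < 64) attr(out, "intval") <- ex
    return(out)
  }
  if (is.name(ex)) {
    v <- env[[as.character(ex)]]
    if (is.null(v)) stop("unknown symbol ", as.character(ex), call. = FALSE)
    return(v)
  }
  op <- as.character(ex[[1L]])
  if (op == "(") return(sm_eval(ex[[2L]], env, N, lead))
  if (op == "-" && length(ex) == 2L) return((MOD_P - sm_eval(ex[[2L]], env, N, lead)) %% MOD_P)
  if (op == "+" && length(ex) == 2L) return(sm_eval(ex[[2L]], env, N, lead))
  a <- sm_eval(ex[[2L]], env, N, lead)
  switch(op,
    "+" = (a + sm_eval(ex[[3L]], env, N, lead)) %% MOD_P,
    "-" = (a - sm_eval(ex[[3L]], env, N, lead)) %% MOD_P,
    "*" = sm_mul(a, sm_eval(ex[[3L]], env, N, lead)),
    "/" = sm_div(a, sm_eval(ex[[3L]], env, N, lead)),
    "^" = {
      b <- sm_eval(ex[[3L]], env, N, lead)
      iv <- attr(b, "intval")
      if (!is.null(iv)) {
        out <- c(1, numeric(N))
        for (i in seq_len(iv)) out <- sm_mul(out, a)
        out
      } else {
        sm_exp(sm_mul(b, sm_log(a, lead)), lead)
      }
    },
    "exp" = sm_exp(a, lead), "log" = sm_log(a, lead), "tanh" = sm_tanh(a, lead),
    stop("unsupported function in jet evaluation: ", op, call. = FALSE)
  )
}

pole_condition <- function() {
  structure(class = c("oncosio_pole", "error", "condition"),
            list(message = "pole at evaluation point", call = NULL))
}

# ---- truncated power series over doubles ------------------------------------

sf_mul <- function(a, b) {
  n <- length(a)
  out <- numeric(n)
  for (k in seq_len(n)) out[k] <- sum(a[1:k] * b[k:1])
  out
}
sf_div <- function(a, b) {
  n <- length(a)
  if (abs(b[1L]) < 1e-12) stop(pole_condition())
  out <- numeric(n)
  out[1L] <- a[1L] / b[1L]
  for (k in seq_len(n)[-1L]) out[k] <- (a[k] - sum(b[2:k] * out[(k - 1):1])) / b[1L]
  out
}
sf_exp <- function(a) {
  n <- length(a)
  out <- numeric(n)
  out[1L] <- exp(a[1L])
  for (k in seq_len(n)[-1L]) {
    i <- 1:(k - 1)
    out[k] <- sum((k - i) * a[k - i + 1L] * out[i]) / (k - 1)
  }
  out
}
sf_log <- function(a) {
  n <- length(a)
  if (a[1L] <= 0) stop(pole_condition())
  out <- numeric(n)
  out[1L] <- log(a[1L])
  for (k in seq_len(n)[-1L]) {
    s <- if (k > 2L) {
      i <- 1:(k - 2)
      sum(i * out[i + 1L] * a[k - i]) / (k - 1)
    } else 0
    out[k] <- (a[k] - s) / a[1L]
  }
  out
}
sf_tanh <- function(a) {
  n <- length(a)
  g <- numeric(n)
  g[1L] <- tanh(a[1L])
  for (k in seq_len(n)[-1L]) {
    w <- -sf_mul(g, g)
    w[1L] <- w[1L] + 1
    i <- 1:(k - 1)
    g[k] <- sum(i * a[i + 1L] * w[k - i]) / (k - 1)
  }
  g
}

sf_eval <- function(ex, env, N) {
  if (is.numeric(ex)) return(c(ex, numeric(N)))
  if (is.name(ex)) {
    v <- env[[as.character(ex)]]
    if (is.null(v)) stop("unknown symbol ", as.character(ex), call. = FALSE)
    return(v)
  }
  op <- as.character(ex[[1L]])
  if (op == "(") return(sf_eval(ex[[2L]], env, N))
  if (op == "-" && length(ex) == 2L) return(-sf_eval(ex[[2L]], env, N))
  if (op == "+" && length(ex) == 2L) return(sf_eval(ex[[2L]], env, N))
  a <- sf_eval(ex[[2L]], env, N)
  switch(op,
    "+" = a + sf_eval(ex[[3L]], env, N),
    "-" = a - sf_eval(ex[[3L]], env, N),
    "*" = sf_mul(a, sf_eval(ex[[3L]], env, N)),
    "/" = sf_div(a, sf_eval(ex[[3L]], env, N)),
    "^" = {
      b <- ex[[3L]]
      if (is.numeric(b) && b == round(b) && b >= 0) {
        out <- c(1, numeric(N))
        for (i in seq_len(b)) out <- sf_mul(out, a)
        out
      } else {
        sf_exp(sf_mul(sf_eval(ex[[3L]], env, N), sf_log(a)))
      }
    },
    "exp" = sf_exp(a), "log" = sf_log(a), "tanh" = sf_tanh(a),
    stop("unsupported function in jet evaluation: ", op, call. = FALSE)
  )
}

# ---- jet propagation --------------------------------------------------------

model_jacobian_exprs <- function(model, measured) {
  measured <- resolve_measured(model, measured)
  dexp <- model$dynamics_rw
  oexp <- model$outputs_rw[measured]
  list(
    f  = dexp,
    h  = oexp,
    Jx = lapply(dexp, function(e) lapply(model$states, function(s) D(e, s))),
    Jp = lapply(dexp, function(e) lapply(model$params, function(s) D(e, s))),
    Hx = lapply(oexp, function(e) lapply(model$states, function(s) D(e, s))),
    Hp = lapply(oexp, function(e) lapply(model$params, function(s) D(e, s))),
    measured = measured
  )
}

# shared driver; `ar` is the arithmetic (modp or double)
jet_oi_matrix <- function(model, measured, point, N, ar) {
  jac <- model_jacobian_exprs(model, measured)
  states <- model$states
  nx <- length(states)
  np <- length(model$params)
  naug <- nx + np
  aug <- augmented_state(model)
  # series environment: states grow order by order; params/inputs fixed series
  xs <- lapply(states, function(s) c(point[[s]], numeric(N)))
  names(xs) <- states
  cenv <- lapply(model$params, function(s) c(point[[s]], numeric(N)))
  names(cenv) <- model$params
  for (u in names(model$inputs)) {
    q <- model$inputs[[u]]
    co <- point[[u]]
    if (q > 0) co <- c(co, unlist(point[paste0(u, "_d", seq_len(q))], use.names = FALSE))
    cenv[[u]] <- c(co, numeric(N + 1L - length(co)))
  }
  ev <- function(ex, env) ar$eval(ex, env, N)
  for (k in 0:(N - 1L)) {
    env <- c(xs, cenv)
    for (j in seq_len(nx)) {
      fk <- ev(jac$f[[j]], env)[k + 1L]
      xs[[j]][k + 2L] <- ar$divint(fk, k + 1L)
    }
  }
  env <- c(xs, cenv)
  Aser <- lapply(jac$Jx, function(rw) lapply(rw, ev, env = env))
  Bser <- lapply(jac$Jp, function(rw) lapply(rw, ev, env = env))
  S <- array(0, c(nx, naug, N + 1L))
  for (j in seq_len(nx)) S[j, j, 1L] <- 1
  for (k in 0:(N - 1L)) {
    ASk <- matrix(0, nx, naug)
    for (i in 0:k) {
      Ai <- matrix(vapply(unlist(Aser, recursive = FALSE), function(s) s[i + 1L], 0),
                   nx, nx, byrow = TRUE)
      Sk <- matrix(S[, , k - i + 1L], nx, naug)
      ASk <- ar$madd(ASk, ar$mmulmat(Ai, Sk))
    }
    Bk <- matrix(vapply(unlist(Bser, recursive = FALSE), function(s) s[k + 1L], 0),
                 nx, np, byrow = TRUE)
    S[, , k + 2L] <- ar$divint(ar$madd(ASk, cbind(matrix(0, nx, nx), Bk)), k + 1L)
  }
  Hxs <- lapply(jac$Hx, function(rw) lapply(rw, ev, env = env))
  Hps <- lapply(jac$Hp, function(rw) lapply(rw, ev, env = env))
  rows <- vector("list", (N + 1L) * length(jac$h))
  ri <- 0L
  for (k in 0:N) {
    for (o in seq_along(jac$h)) {
      row <- numeric(naug)
      for (i in 0:k) {
        hx <- vapply(Hxs[[o]], function(s) s[i + 1L], 0)
        row <- ar$madd(row, as.vector(ar$mmulmat(matrix(hx, 1L), matrix(S[, , k - i + 1L], nx, naug))))
      }
      hp <- vapply(Hps[[o]], function(s) s[k + 1L], 0)
      row[(nx + 1L):naug] <- ar$madd(row[(nx + 1L):naug], hp)
      ri <- ri + 1L
      rows[[ri]] <- row
    }
  }
  M <- do.call(rbind, rows)
  colnames(M) <- aug
  M
}

ar_modp <- function() {
  memo <- new.env(parent = emptyenv())
  lead <- function(op, a0) {
    key <- paste0(op, "@", a0)
    if (is.null(memo[[key]])) memo[[key]] <- sample(2:(MOD_P - 2), 1L)
    memo[[key]]
  }
  list(
    eval = function(ex, env, N) sm_eval(ex, env, N, lead),
    divint = function(x, k) mod_mul(x, mod_inv(k %% MOD_P)),
    madd = function(a, b) (a + b) %% MOD_P,
    mmulmat = mod_mat_mul
  )
}

ar_double <- function() {
  list(
    eval = function(ex, env, N) sf_eval(ex, env, N),
    divint = function(x, k) x / k,
    madd = function(a, b) a + b,
    mmulmat = function(A, B) A %*% B
  )
}

# exact OI matrix over GF(p) at a seeded random field point
jet_oi_modp <- function(model, measured = NULL, seed = 1L, N = NULL) {
  if (is.null(N)) N <- n_aug(model) - 1L
  pt <- field_point(model, seed)
  with_seed(seed + 13L, jet_oi_matrix(model, measured, as.list(pt), N, ar_modp()))
}

# float OI matrix at a real point (nullspace estimation for witnesses)
jet_oi_double <- function(model, measured = NULL, point, N = NULL) {
  if (is.null(N)) N <- n_aug(model) - 1L
  point <- c(as.list(point), as.list(model$known_constants))
  repeat {
    M <- jet_oi_matrix(model, measured, point, N, ar_double())
    if (all(is.finite(M)) && max(abs(M)) < 1e120) return(M)
    if (N <= 4L) stop("jet overflow at evaluation point", call. = FALSE)
    N <- max(4L, N %/% 2L)
  }
}
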
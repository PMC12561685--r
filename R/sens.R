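# Timepoint-sampled output sensitivity matrix.
#
# Integrates the state ODE jointly with the forward variational equations
# dS/dt = (df/dx) S + [0 | df/dtheta], S(0) = [I | 0], and stacks
# (dh/dx) S(t_k) + [0 | dh/dtheta] over the requested timepoints. The
# variational Jacobians are derived symbolically once, then evaluated
# numerically, which avoids finite-difference noise.

#' Build a timepoint sensitivity matrix
#'
#' @param model an `sio_model`.
#' @param measured character vector of measured output names.
#' @param point named numeric point (see [generic_point()]).
#' @param timepoints strictly increasing; needs `K * ny >= nx + ntheta` rows
#'   for a full-rank test to be possible.
#' @param rtol,atol integration tolerances.
#' @return an object of class `sio_sens`: the numeric matrix with row/column
#'   labels plus metadata.
#' @export
build_sensitivity_matrix <- function(model, measured = NULL, point,
                                     timepoints = NULL, rtol = 1e-11,
                                     atol = 1e-13) {
  jac <- model_jacobian_exprs(model, measured)
  measured <- jac$measured
  nx <- length(model$states)
  np <- length(model$params)
  naug <- nx + np
  ny <- length(measured)
  if (is.null(timepoints)) {
    timepoints <- seq(0, model$horizon, length.out = max(4L * naug, 8L))
  }
  K <- length(timepoints)
  if (K * ny < naug) {
    stop("need K * ny >= nx + ntheta timepoint rows (got ", K * ny, " < ",
         naug, ")", call. = FALSE)
  }
  penv <- list2env(c(as.list(point[model$params]),
                     as.list(model$known_constants)), parent = math_env)
  state_env <- function(y, t) {
    env <- list2env(as.list(stats::setNames(y[seq_len(nx)], model$states)),
                    parent = penv)
    for (u in names(model$inputs)) {
      assign(u, input_value_at(model, point, t)[[u]], envir = env)
    }
    env
  }
  evl <- function(exprs, env) vapply(exprs, eval, 0, envir = env)
  rhs <- function(t, y, parms) {
    env <- state_env(y, t)
    f <- evl(jac$f, env)
    A <- matrix(evl(unlist(jac$Jx, recursive = FALSE), env), nx, nx, byrow = TRUE)
    B <- matrix(evl(unlist(jac$Jp, recursive = FALSE), env), nx, np, byrow = TRUE)
    S <- matrix(y[-seq_len(nx)], nx, naug)
    dS <- A %*% S
    if (np > 0) dS[, nx + seq_len(np)] <- dS[, nx + seq_len(np)] + B
    list(c(f, as.vector(dS)))
  }
  y0 <- c(point[model$states], as.vector(cbind(diag(nx), matrix(0, nx, np))))
  tt <- if (timepoints[1] == 0) timepoints else c(0, timepoints)
  sol <- deSolve::lsoda(y0, tt, rhs, rtol = rtol, atol = atol)
  sol <- sol[match(timepoints, sol[, 1L]), , drop = FALSE]
  if (anyNA(sol) || any(!is.finite(sol))) {
    stop("integration failure while building sensitivities", call. = FALSE)
  }
  rows <- matrix(0, K * ny, naug)
  labels <- character(K * ny)
  for (i in seq_len(K)) {
    y <- sol[i, -1L]
    env <- state_env(y, timepoints[i])
    S <- matrix(y[-seq_len(nx)], nx, naug)
    for (o in seq_len(ny)) {
      hx <- evl(jac$Hx[[o]], env)
      hp <- evl(jac$Hp[[o]], env)
      rows[(i - 1L) * ny + o, ] <- as.vector(hx %*% S) + c(numeric(nx), hp)
      labels[(i - 1L) * ny + o] <- sprintf("t=%.6g/%s", timepoints[i], measured[o])
    }
  }
  colnames(rows) <- augmented_state(model)
  rownames(rows) <- labels
  structure(list(matrix = rows, timepoints = timepoints, point = point,
                 measured = measured, acronym = model$acronym,
                 tolerances = c(rtol = rtol, atol = atol)),
            class = "sio_sens")
}

#' @export
print.sio_sens <- function(x, ...) {
  cat(sprintf("<sio_sens %s | y = {%s}>  %d x %d over %d timepoints\n",
              x$acronym, paste(x$measured, collapse = ", "),
              nrow(x$matrix), ncol(x$matrix), length(x$timepoints)))
  invisible(x)
}

#' Export a sensitivity matrix as CSV
#' @param sens an `sio_sens`.
#' @param path file path.
#' @export
write_sensitivities <- function(sens, path) {
  utils::write.csv(as.data.frame(sens$matrix), path, row.names = TRUE)
  invisible(path)
}

#' Numerical rank with a tolerance-and-gap policy
#'
#' Rank is the number of singular values above `rtol` times the largest
#' (after row and column normalisation, which does not change rank). The
#' verdict is accepted only when the relative gap at the cut exceeds
#' `gap_factor`; otherwise a condition of class `oncosio_ambiguous_rank` is
#' raised and the caller should resample or extend the timepoints.
#'
#' @param M numeric matrix (or `sio_sens`).
#' @param rtol relative singular value tolerance.
#' @param gap_factor minimal acceptable ratio sigma_r / sigma_(r+1).
#' @return integer rank.
#' @export
numeric_rank <- function(M, rtol = 1e-6, gap_factor = 1e3) {
  if (inherits(M, "sio_sens")) M <- M$matrix
  stopifnot(all(is.finite(M)))
  rn <- sqrt(rowSums(M^2))
  Mn <- M / pmax(rn, 1e-300)
  cn <- sqrt(colSums(Mn^2))
  Mn <- sweep(Mn, 2L, pmax(cn, 1e-300), "/")
  sv <- svd(Mn, nu = 0, nv = 0)$d
  if (sv[1L] == 0) return(0L)
  r <- sum(sv > rtol * sv[1L])
  if (r < length(sv)) {
    gap <- sv[r] / max(sv[r + 1L], .Machine$double.xmin)
    if (gap < gap_factor) {
      stop(structure(class = c("oncosio_ambiguous_rank", "error", "condition"),
                     list(message = sprintf(
                       "ambiguous numerical rank (gap %.3g < %.3g at r = %d)",
                       gap, gap_factor, r), call = NULL)))
    }
  }
  as.integer(r)
}
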
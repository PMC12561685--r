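# Numerical simulation of catalogue models and closed-form oracles.

input_value_at <- function(model, point, t) {
  vals <- list()
  for (u in names(model$inputs)) {
    q <- model$inputs[[u]]
    v <- point[[u]]
    if (q > 0) {
      for (j in seq_len(q)) v <- v + point[[paste0(u, "_d", j)]] * t^j / factorial(j)
    }
    vals[[u]] <- v
  }
  vals
}

#' Simulate a model at a point
#'
#' Integrates \eqn{\dot x = f(u(t), x, \theta)} with the stiff-capable `lsoda`
#' solver. Inputs are realised as the polynomials implied by the point's input
#' derivative values. Tight default tolerances because witness-pair equality
#' claims depend on them.
#'
#' @param model an `sio_model`.
#' @param point named vector as produced by [generic_point()]; must cover all
#'   states, parameters and input values.
#' @param times increasing time vector.
#' @param rtol,atol integration tolerances.
#' @return a tibble of class `sio_trajectory` with columns `t`, one per state
#'   and one per output.
#' @export
sio_simulate <- function(model, point, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(all(diff(times) > 0) || length(times) == 1L)
  nx <- length(model$states)
  penv <- list2env(c(as.list(point[model$params]),
                     as.list(model$known_constants)), parent = math_env)
  dyn_body <- as.call(c(quote(c), unname(model$dynamics)))
  out_body <- as.call(c(quote(c), unname(model$outputs)))
  rhs <- function(t, y, parms) {
    env <- list2env(as.list(stats::setNames(y, model$states)), parent = penv)
    for (u in names(model$inputs)) {
      assign(u, input_value_at(model, point, t)[[u]], envir = env)
    }
    list(eval(dyn_body, env))
  }
  t0 <- times
  if (times[1] != 0) t0 <- c(0, times)
  sol <- tryCatch(
    deSolve::lsoda(point[model$states], t0, rhs, rtol = rtol, atol = atol),
    warning = function(w) {
      stop("integration failure: ", conditionMessage(w), call. = FALSE)
    })
  sol <- sol[match(times, sol[, 1]), , drop = FALSE]
  if (anyNA(sol) || any(!is.finite(sol))) {
    reached <- max(sol[stats::complete.cases(sol), 1], 0)
    stop("integration failure (blow-up); time reached: ", reached, call. = FALSE)
  }
  outs <- t(apply(sol, 1L, function(row) {
    env <- list2env(as.list(stats::setNames(row[-1L], model$states)), parent = penv)
    for (u in names(model$inputs)) {
      assign(u, input_value_at(model, point, row[[1L]])[[u]], envir = env)
    }
    eval(out_body, env)
  }))
  if (length(model$outputs) == 1L) outs <- matrix(outs, ncol = 1L)
  colnames(outs) <- names(model$outputs)
  # outputs named like a state (identity measurements) would duplicate the
  # state column; keep only genuinely derived outputs as extra columns
  extra <- setdiff(names(model$outputs), model$states)
  tr <- tibble::as_tibble(cbind(data.frame(t = sol[, 1L]),
                                as.data.frame(sol[, -1L, drop = FALSE]),
                                as.data.frame(outs[, extra, drop = FALSE])))
  names(tr) <- c("t", model$states, extra)
  attr(tr, "acronym") <- model$acronym
  attr(tr, "states") <- model$states
  attr(tr, "output_names") <- names(model$outputs)
  attr(tr, "tolerances") <- c(rtol = rtol, atol = atol)
  class(tr) <- c("sio_trajectory", class(tr))
  tr
}

#' Closed-form solutions of the classical growth laws
#'
#' Evaluates the explicit analytic solution (where one exists) at time `t`;
#' the integration oracle for [sio_simulate()]. Supported: EXP1, EXP2, EXP3,
#' POW, GOM1, GOM2, LOG, BERT, RAD1.
#'
#' @param acronym model acronym.
#' @param point named parameter/initial-condition vector (as [generic_point()]).
#' @param t time (vectorised).
#' @return the model output value(s) at `t`, or `NULL` if no closed form is
#'   available.
#' @export
closed_form <- function(acronym, point, t) {
  p <- as.list(point)
  switch(acronym,
    EXP1 = p$V * exp(p$lambda * t),
    EXP2 = p$K * p$V / (p$V + (p$K - p$V) * exp(-p$lambda * t)),
    EXP3 = p$K * p$V / (p$V^p$theta + (p$K^p$theta - p$V^p$theta) *
                          exp(-p$lambda * t))^(1 / p$theta),
    POW  = (p$N^(1 - p$gamma) + (1 - p$gamma) * p$a * t)^(1 / (1 - p$gamma)),
    GOM1 = p$N * exp(p$g / p$b * (1 - exp(-p$b * t))),
    GOM2 = p$K * exp(log(p$N / p$K) * exp(-p$alpha * t)),
    LOG  = p$N * p$K / (p$N + (p$K - p$N) * exp(-p$a * t)),
    BERT = (p$a / p$b + (p$N^(1 - p$gamma) - p$a / p$b) *
              exp(-(1 - p$gamma) * p$b * t))^(1 / (1 - p$gamma)),
    RAD1 = {
      lump <- p$alpha * p$d + p$beta * p$d^2
      iu <- p$u * t + if (!is.null(p$u_d1)) p$u_d1 * t^2 / 2 else 0
      p$V * exp(p$lambda * t - lump * iu)
    },
    NULL
  )
}

#' Simulated data with additive measurement noise
#'
#' Output trajectories with i.i.d. Gaussian noise added to each measured
#' output; `noise_sd = 0` reduces to [sio_simulate()]. Structural analysis
#' itself is noise-free; this generator supports downstream demonstrations.
#'
#' @inheritParams sio_simulate
#' @param noise_sd standard deviation of the additive noise (>= 0).
#' @param seed integer seed.
#' @export
generate_dataset <- function(model, point, times, noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0)
  tr <- sio_simulate(model, point, times)
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(length(times) * length(model$outputs),
                                                 sd = noise_sd),
                                    nrow = length(times)))
    for (j in seq_along(model$outputs)) {
      nm <- names(model$outputs)[j]
      tr[[nm]] <- tr[[nm]] + noise[, j]
    }
  }
  attr(tr, "noise_sd") <- noise_sd
  attr(tr, "seed") <- seed
  tr
}

#' Export a trajectory as CSV
#'
#' Header `t,<state...>,<output...>`.
#' @param trajectory an `sio_trajectory`.
#' @param path file path.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
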
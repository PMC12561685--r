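# Independent oracles used to cross-check the engines.

# Brute-force local rank oracle: central finite differences of the simulated
# outputs with respect to every augmented coordinate. Depends only on the
# integrator, not on the Lie/jet/variational code paths.
fd_sens_rank <- function(model, measured, point, times, h = 1e-6,
                         rtol = 1e-5) {
  aug <- augmented_state(model)
  cols <- lapply(aug, function(s) {
    p1 <- point; p1[[s]] <- p1[[s]] + h
    p2 <- point; p2[[s]] <- p2[[s]] - h
    tr1 <- sio_simulate(model, p1, times)
    tr2 <- sio_simulate(model, p2, times)
    (as.vector(as.matrix(tibble::as_tibble(tr1)[, measured])) -
       as.vector(as.matrix(tibble::as_tibble(tr2)[, measured]))) / (2 * h)
  })
  numeric_rank(do.call(cbind, cols), rtol = rtol)
}

# numeric value of the order-k Lie derivative of one output at a point,
# via the symbolic engine's internals (auxiliary symbols evaluated honestly)
lie_value <- function(model, output, order, point) {
  lc <- oncosio:::lie_context(model, output)
  L <- lc$h[[output]]
  for (k in seq_len(order)) L <- oncosio:::lie_step(L, lc)
  vals <- oncosio:::ctx_values(lc$ctx, c(point, model$known_constants))
  stopifnot(!is.null(vals))
  oncosio:::p_eval(L, vals)
}
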
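# Generic evaluation points.
#
# Local structural analysis is performed at a generic point of the augmented
# state (plus input values). Floating-point work (simulation oracles,
# witnesses) samples rationals k/7 with k = 8..21, i.e. values in (1.14, 3):
# strictly above 1 to avoid accidental cancellations and poles at 0, and small
# enough that the stiffest catalogue models stay finite over their horizons.
# Symbols declared on the unit interval (fractions, exponents in (0,1)) sample
# k/71 with k = 8..63. Exact-rank work samples uniform field elements instead.

#' Sample a generic evaluation point
#'
#' Returns a named vector covering every state, parameter and input value of
#' the model (an input with `q` nonzero derivatives contributes `q + 1`
#' values: `u, u_d1, ..., u_dq`). Points at which some model expression has a
#' vanishing denominator are rejected and resampled.
#'
#' @param model an `sio_model`.
#' @param seed integer seed.
#' @return named numeric vector; attribute `"seed"` records the seed.
#' @export
generic_point <- function(model, seed = 1L) {
  syms <- c(model$states, model$params, input_symbols(model))
  for (attempt in 0:49) {
    pt <- with_seed(seed + 1000L * attempt, {
      v <- sample(8:21, length(syms), replace = TRUE) / 7
      u <- syms %in% model$unit_symbols
      if (any(u)) v[u] <- sample(8:63, sum(u), replace = TRUE) / 71
      stats::setNames(v, syms)
    })
    vals <- c(pt, model$known_constants)
    ok <- all(vapply(c(model$dynamics, model$outputs),
                     function(ex) !is.na(eval_expr(ex, vals)), TRUE))
    if (ok) {
      attr(pt, "seed") <- seed
      return(pt)
    }
  }
  stop("sampling failure: no admissible generic point found", call. = FALSE)
}

# uniform field point for exact-rank evaluation
field_point <- function(model, seed = 1L) {
  syms <- c(model$states, model$params, input_symbols(model))
  with_seed(seed, stats::setNames(sample(2:(MOD_P - 2), length(syms), replace = TRUE), syms))
}

# evaluate under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
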
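test_that("low-order Lie derivatives match hand calculation", {
  m <- get_model("EXP1")
  l0 <- lie_derivative(m, "V", order = 0)
  expect_equal(format(l0$V, vars = attr(l0$V, "vars")), "V")
  l1 <- lie_derivative(m, "V", order = 1)
  expect_equal(format(l1$V, vars = attr(l1$V, "vars")), "V*lambda")

  # independent oracle: hand differentiation of the logistic law gives
  # L1 = a N (1 - N/K); compare numerically at random points
  m <- get_model("LOG")
  for (s in 1:5) {
    pt <- generic_point(m, s)
    want <- pt[["a"]] * pt[["N"]] * (1 - pt[["N"]] / pt[["K"]])
    expect_equal(lie_value(m, "N", 1, pt), unname(want), tolerance = 1e-12)
  }
})

test_that("the OI matrix of the exponential model is [[1,0],[lambda,V]]", {
  m <- get_model("EXP1")
  oi <- build_oi(m, max_order = 1)
  expect_equal(oi_dump(oi), c("1", "0", "lambda", "V"))
  M <- oncosio:::oi_eval(oi, c(V = 2, lambda = 3))
  expect_equal(unname(M), rbind(c(1, 0), c(3, 2)))
  # hand Gaussian elimination on [[1,0],[3,2]] gives rank 2
  expect_equal(generic_rank(oi), 2L)
})

test_that("order-0 and power-law OI matrices have the documented shape", {
  m <- get_model("POW")
  oi0 <- build_oi(m, max_order = 0)
  expect_length(oi_dump(oi0), 3L)           # ny rows x naug columns
  oi2 <- build_oi(m, max_order = 2)
  M <- oncosio:::oi_eval(oi2, generic_point(m, 1))
  expect_equal(dim(M), c(3L, 3L))
  expect_equal(unname(M[1L, ]), c(1, 0, 0))
  expect_error(build_oi(m, max_order = 3), "cap")
})

test_that("generic rank is exact, bounded and monotone in the order", {
  expect_equal(oncosio:::rank_modp(matrix(0, 3, 4)), 0L)

  m <- get_model("LV")
  oi <- saturated_oi(m, "total", seed = 1)
  ranks <- attr(oi, "ranks")
  expect_true(all(diff(ranks) >= 0))
  expect_true(all(ranks <= 8))
  expect_equal(attr(oi, "rank"), 8L)

  # radiotherapy base model: nullity 2 from the two-dimensional symmetry of
  # the dose lump alpha*d + beta*d^2
  oi <- saturated_oi(get_model("RAD1"), "V", seed = 1)
  expect_equal(attr(oi, "rank"), 3L)
})

test_that("rank is invariant to parameter declaration order and duplicate outputs", {
  base <- sio_model("LVP", states = c("VS", "VR"),
    params = c("lambda_S", "lambda_R", "K_S", "K_R", "gamma_R", "gamma_S"),
    dynamics = c(VS = "lambda_S*VS*(1 - VS/K_S - gamma_R*VR/K_S)",
                 VR = "lambda_R*VR*(1 - VR/K_R - gamma_S*VS/K_R)"),
    outputs = c(VS = "VS"))
  perm <- sio_model("LVQ", states = c("VS", "VR"),
    params = c("gamma_S", "K_R", "lambda_R", "gamma_R", "K_S", "lambda_S"),
    dynamics = c(VS = "lambda_S*VS*(1 - VS/K_S - gamma_R*VR/K_S)",
                 VR = "lambda_R*VR*(1 - VR/K_R - gamma_S*VS/K_R)"),
    outputs = c(VS = "VS"))
  r1 <- attr(saturated_oi(base, "VS", seed = 3), "rank")
  r2 <- attr(saturated_oi(perm, "VS", seed = 3), "rank")
  expect_equal(r1, r2)

  dup <- sio_model("LVD", states = c("VS", "VR"),
    params = c("lambda_S", "lambda_R", "K_S", "K_R", "gamma_R", "gamma_S"),
    dynamics = c(VS = "lambda_S*VS*(1 - VS/K_S - gamma_R*VR/K_S)",
                 VR = "lambda_R*VR*(1 - VR/K_R - gamma_S*VS/K_R)"),
    outputs = c(y1 = "VS", y2 = "VS"))
  r3 <- attr(saturated_oi(dup, c("y1", "y2"), seed = 3), "rank")
  expect_equal(r3, r1)
})

test_that("generic rank agrees with a brute-force finite-difference oracle", {
  # oracle uses only the integrator: rank of d(output trajectory)/d(x0, theta)
  for (a in c("EXP1", "EXP2", "LOG")) {
    m <- get_model(a)
    pt <- generic_point(m, 4)
    times <- seq(0, 1, length.out = 4 * length(augmented_state(m)))
    r_fd <- fd_sens_rank(m, names(m$outputs)[1], pt, times)
    r_sym <- attr(saturated_oi(m, names(m$outputs)[1], seed = 4), "rank")
    expect_equal(r_sym, r_fd)
  }
})

test_that("the expression-swell guard refuses oversized symbolic analyses", {
  m <- get_model("CICV")
  expect_error(
    classify(m, "I", backend = "symbolic", term_budget = 2e3),
    "swell")
  # auto falls back to the numeric backend instead
  res <- classify(m, "I", backend = "auto", seed = 1, term_budget = 2e3)
  expect_equal(res$backend, "numeric")
  expect_equal(res$rank, 10L)
})
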
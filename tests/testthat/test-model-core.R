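test_that("model construction validates symbols and arity", {
  m <- sio_model("EXP1", states = "V", params = "lambda",
                 dynamics = c(V = "lambda*V"), outputs = c(V = "V"))
  expect_s3_class(m, "sio_model")
  expect_equal(length(m$states), 1L)
  expect_equal(length(m$params), 1L)

  expect_error(
    sio_model("X", states = "V", params = "lambda",
              dynamics = c(V = "lambda*W"), outputs = c(V = "V")),
    "W")
  expect_error(
    sio_model("X", states = c("A", "B"), params = "k",
              dynamics = c(A = "k*A"), outputs = c(A = "A")),
    "arity")
  expect_error(
    sio_model("X", states = "V", params = "lambda",
              dynamics = c(V = "lambda*V"), outputs = character(0)),
    "output")
})

test_that("augmented state is states then parameters, in declaration order", {
  expect_equal(augmented_state(get_model("EXP1")), c("V", "lambda"))
  expect_length(augmented_state(get_model("CRS")), 31L)
  expect_equal(augmented_state(get_model("POW")), c("N", "a", "gamma"))
  lv <- get_model("LV")
  expect_equal(augmented_state(lv)[1:2], lv$states)
})

test_that("models round-trip through the model-definition file", {
  for (a in c("RAD2", "LV", "CYCLE", "CICV")) {
    m <- get_model(a)
    f <- withr::local_tempfile(fileext = ".yaml")
    write_model(m, f)
    m2 <- read_model(f)
    expect_identical(m2$acronym, m$acronym)
    expect_identical(m2$states, m$states)
    expect_identical(m2$params, m$params)
    expect_identical(m2$inputs, m$inputs)
    expect_identical(m2$dynamics_src, m$dynamics_src)
    expect_identical(m2$outputs_src, m$outputs_src)
  }
})

test_that("equilibria simulate as constants", {
  m <- get_model("EXP1")
  tr <- sio_simulate(m, c(V = 1, lambda = 0), seq(0, 2, length.out = 9))
  expect_equal(tr$V, rep(1, 9), tolerance = 1e-9)

  m <- get_model("LOG")
  tr <- sio_simulate(m, c(N = 10, a = 1.5, K = 10), seq(0, 2, length.out = 9))
  expect_equal(tr$N, rep(10, 9), tolerance = 1e-9)
})

test_that("simulation matches printed explicit solutions", {
  # frozen value: V(t) = V0 exp(lambda t) at V0 = 2, lambda = 0.5, t = 2
  m <- get_model("EXP1")
  tr <- sio_simulate(m, c(V = 2, lambda = 0.5), c(1, 2))
  expect_equal(tr$V[2], 2 * exp(1), tolerance = 1e-8)

  # carrying-capacity equilibrium of the von Bertalanffy law
  m <- get_model("BERT")
  a <- 2; b <- 1.5; gam <- 0.4
  K <- (a / b)^(1 / (1 - gam))
  tr <- sio_simulate(m, c(N = K, a = a, b = b, gamma = gam),
                     seq(0, 1, length.out = 5))
  expect_equal(tr$N, rep(K, 5), tolerance = 1e-8)

  # the decaying-rate Gompertz form approaches plain exponential growth as
  # the decay parameter vanishes
  m <- get_model("GOM1")
  pt <- c(N = 2, g = 1.3, b = 1e-9)
  expect_equal(closed_form("GOM1", pt, 1.5), 2 * exp(1.3 * 1.5),
               tolerance = 1e-6)
})

test_that("simulate agrees with every printed closed form at generic points", {
  for (a in c("EXP3", "LOG", "RAD1")) {
    m <- get_model(a)
    for (s in 1:2) {
      pt <- generic_point(m, s)
      tt <- seq(0, m$horizon, length.out = 20)
      tr <- sio_simulate(m, pt, tt)
      cf <- closed_form(a, pt, tt)
      ycol <- if (a %in% c("EXP3", "RAD1")) "V" else "N"
      expect_lt(max(abs(tr[[ycol]] - cf) / pmax(abs(cf), 1e-12)), 1e-6)
    }
  }
  expect_null(closed_form("CRS", generic_point(get_model("CRS"), 1), 1))
})

test_that("generic points are admissible and reproducible", {
  m <- get_model("CICV")
  p1 <- generic_point(m, 11)
  p2 <- generic_point(m, 11)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0))
  # covers states, params and input derivative values
  expect_true(all(c(m$states, m$params, "beta1", "beta1_d1", "gamma",
                    "gamma_d1") %in% names(p1)))
  # unit-interval symbols stay inside (0, 1)
  pb <- generic_point(get_model("BERT"), 3)
  expect_lt(pb[["gamma"]], 1)
  expect_gt(pb[["gamma"]], 0)
})

test_that("trajectory export writes the documented CSV layout", {
  m <- get_model("LV")
  tr <- sio_simulate(m, generic_point(m, 2), seq(0, 0.1, length.out = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  got <- utils::read.csv(f)
  expect_equal(names(got), c("t", "VS", "VR", "total"))
  expect_equal(got$total, got$VS + got$VR, tolerance = 1e-12)
})
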
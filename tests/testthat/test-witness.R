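test_that("null directions are supported on the unidentifiable symbols", {
  m <- get_model("RAD1")
  res <- classify(m, "V", seed = 1)
  v <- null_direction(m, "V", generic_point(m, 1), res, seed = 1)
  expect_setequal(names(v)[abs(v) > 1e-6], c("alpha", "beta", "d"))
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)

  m <- get_model("LV")
  res <- classify(m, "VS", seed = 1)
  v <- null_direction(m, "VS", generic_point(m, 1), res, seed = 1)
  expect_setequal(names(v)[abs(v) > 1e-6],
                  c("VR", "K_R", "gamma_R", "gamma_S"))

  # fully identifiable scenario: no-direction signal
  m <- get_model("EXP1")
  res <- classify(m, "V", seed = 1)
  expect_error(null_direction(m, "V", generic_point(m, 1), res),
               class = "oncosio_full_rank")
})

test_that("the dose-lump witness of the radiotherapy base model is exact", {
  # (alpha, beta, d) = (0.3, 0.1, 1) vs (0.1, 0.3, 1): both have
  # alpha*d + beta*d^2 = 0.4, so V(t) must coincide exactly
  m <- get_model("RAD1")
  base <- c(V = 2, lambda = 1.5, u = 1, u_d1 = 0.5)
  pa <- c(base, alpha = 0.3, beta = 0.1, d = 1)
  pb <- c(base, alpha = 0.1, beta = 0.3, d = 1)
  tt <- seq(0, 0.05, length.out = 100)
  ya <- sio_simulate(m, pa, tt)$V
  yb <- sio_simulate(m, pb, tt)$V
  expect_lt(max(abs(ya - yb)), 1e-10)

  wit <- make_witness(m, "V", seed = 1)
  expect_lt(wit$output_discrepancy, 1e-6)
  expect_gt(wit$param_distance, 0.01)
  lump <- function(p) p[["alpha"]] * p[["d"]] + p[["beta"]] * p[["d"]]^2
  expect_equal(lump(wit$point_a), lump(wit$point_b), tolerance = 1e-12)
})

test_that("the Lotka-Volterra scaling witness leaves the measured volume unchanged", {
  # (VR0, K_R, gamma_R, gamma_S) -> (c VR0, c K_R, gamma_R/c, c gamma_S)
  m <- get_model("LV")
  pa <- generic_point(m, 3)
  c0 <- 2
  pb <- pa
  pb[["VR"]] <- pa[["VR"]] * c0
  pb[["K_R"]] <- pa[["K_R"]] * c0
  pb[["gamma_R"]] <- pa[["gamma_R"]] / c0
  pb[["gamma_S"]] <- pa[["gamma_S"]] * c0
  tt <- seq(0, m$horizon, length.out = 100)
  expect_lt(max(abs(sio_simulate(m, pa, tt)$VS - sio_simulate(m, pb, tt)$VS)),
            1e-8)

  wit <- make_witness(m, "VS", seed = 1)
  expect_lt(wit$output_discrepancy, 1e-6)
  expect_gt(wit$param_distance, 0.01)
  # the symmetry moves exactly the symbols classified negative
  moved <- names(wit$point_a)[abs(wit$point_a - wit$point_b) > 1e-12]
  expect_setequal(moved, wit$free)
})

test_that("no witness exists for a fully identifiable scenario", {
  expect_error(make_witness(get_model("EXP1"), "V", seed = 1),
               class = "oncosio_full_rank")
})

test_that("a numerically walked witness passes on an interacting model", {
  m <- get_model("HCART")
  res <- classify(m, "T", backend = "numeric", seed = 1)
  wit <- make_witness(m, "T", seed = 1, result = res)
  expect_lt(wit$output_discrepancy, 1e-6)
  expect_gt(wit$param_distance, 0.01)
  expect_true(all(wit$free %in% c("CT", "CM", "phi", "rho", "gamma")))
  # identifiable coordinates are untouched by the walk
  fixed <- setdiff(names(wit$point_a), wit$free)
  expect_equal(wit$point_a[fixed], wit$point_b[fixed], tolerance = 1e-12)
})

test_that("witness output agreement degrades gracefully with looser tolerances", {
  m <- get_model("LV")
  wit <- make_witness(m, "VS", seed = 2)
  tt <- wit$trajectory_a$t
  loose_a <- sio_simulate(m, wit$point_a, tt, rtol = 2e-11, atol = 2e-13)
  loose_b <- sio_simulate(m, wit$point_b, tt, rtol = 2e-11, atol = 2e-13)
  disc <- max(abs(loose_a$VS - loose_b$VS))
  expect_lt(disc, max(wit$output_discrepancy, 1e-12) * 10)
})

test_that("distinguishability checks support full verdicts and expose symmetries", {
  expect_true(local_distinguishability_check(get_model("EXP1"), "V", seed = 1))
  expect_true(local_distinguishability_check(get_model("NECR"), "Nt", seed = 1))
  # negative control: a perturbation along the dose-lump symmetry of RAD1
  # leaves the output unchanged
  m <- get_model("RAD1")
  pt <- generic_point(m, 1)
  forced <- c(alpha = 0.1, beta = -0.1 / pt[["d"]])
  expect_false(local_distinguishability_check(m, "V", seed = 1,
                                              direction = forced))
})

test_that("noisy dataset generation is calibrated and reproducible", {
  m <- get_model("EXP1")
  pt <- generic_point(m, 1)
  tt <- seq(0, 1, length.out = 50)

  # noise_sd = 0 reduces to plain simulation
  expect_equal(generate_dataset(m, pt, tt, noise_sd = 0)$V,
               sio_simulate(m, pt, tt)$V)

  # additive noise with sd 0.1: residual spread against the explicit solution
  ds <- generate_dataset(m, pt, tt, noise_sd = 0.1, seed = 42)
  res <- ds$V - closed_form("EXP1", pt, tt)
  expect_gt(stats::sd(res), 0.07)
  expect_lt(stats::sd(res), 0.13)

  # a fixed seed reproduces a byte-identical CSV
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_trajectory(generate_dataset(m, pt, tt, 0.1, seed = 7), f1)
  write_trajectory(generate_dataset(m, pt, tt, 0.1, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("witness export writes paired trajectories and metadata", {
  wit <- make_witness(get_model("RAD1"), "V", seed = 1)
  dir <- withr::local_tempdir()
  export_witness(wit, dir, stem = "w")
  expect_true(file.exists(file.path(dir, "w_a.csv")))
  expect_true(file.exists(file.path(dir, "w_b.csv")))
  meta <- jsonlite::fromJSON(file.path(dir, "w.json"))
  expect_equal(meta$acronym, "RAD1")
  expect_lt(meta$output_discrepancy, 1e-6)
})
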
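test_that("classification reproduces known single-scenario verdicts", {
  # saturated logistic growth: everything identifiable and observable
  res <- classify(get_model("EXP2"), "V", seed = 1)
  expect_true(res$full)
  expect_equal(unname(res$verdicts[c("lambda", "K")]),
               c("identifiable", "identifiable"))
  expect_equal(unname(res$verdicts["V"]), "observable")

  # competing populations, resistant volume measured
  res <- classify(get_model("LV"), "VR", seed = 1)
  vp <- res$verdicts
  expect_setequal(names(vp)[vp == "identifiable"],
                  c("lambda_S", "lambda_R", "K_R"))
  expect_setequal(names(vp)[vp == "unidentifiable"],
                  c("K_S", "gamma_R", "gamma_S"))
  expect_equal(unname(vp["VS"]), "unobservable")

  # radiotherapy on the carrying capacity: fully identifiable
  res <- classify(get_model("RCAP"), "V", seed = 1)
  expect_true(res$full)

  # CAR-T model with tumour burden measured (numeric backend)
  res <- classify(get_model("HCART"), "T", backend = "numeric", seed = 1)
  vp <- res$verdicts
  expect_setequal(names(vp)[vp == "identifiable"],
                  c("epsilon", "theta", "alpha", "mu", "r", "b"))
  expect_setequal(names(vp)[vp == "unidentifiable"], c("phi", "rho", "gamma"))
  expect_setequal(names(vp)[vp == "unobservable"], c("CT", "CM"))
})

test_that("verdicts are seed-stable", {
  for (spec in list(list("EXP3", "V"), list("LV", "VS"), list("RAD1", "V"))) {
    m <- get_model(spec[[1]])
    v1 <- classify(m, spec[[2]], seed = 1)$verdicts
    for (s in 2:5) {
      expect_identical(classify(m, spec[[2]], seed = s)$verdicts, v1,
                       info = paste(spec[[1]], "seed", s))
    }
  }
  m <- get_model("LEUK")
  v1 <- classify(m, c("T", "TN", "E"), backend = "numeric", seed = 1)$verdicts
  for (s in 2:5) {
    expect_identical(
      classify(m, c("T", "TN", "E"), backend = "numeric", seed = s)$verdicts, v1)
  }
})

test_that("column-removal verdicts agree with a nullspace-projection oracle", {
  # brute force on small models: a symbol is unidentifiable iff the projection
  # of its coordinate axis onto the numerical nullspace is appreciable
  for (spec in list(list("RAD1", "V"), list("LV", "VS"))) {
    m <- get_model(spec[[1]])
    res <- classify(m, spec[[2]], seed = 1)
    pt <- generic_point(m, 1)
    M <- oncosio:::jet_oi_double(m, spec[[2]], pt)
    M <- M / pmax(sqrt(rowSums(M^2)), 1e-300)
    V <- svd(M)$v
    null_basis <- V[, seq.int(res$rank + 1L, ncol(M)), drop = FALSE]
    proj <- sqrt(rowSums(null_basis^2))
    names(proj) <- colnames(M)
    negative <- res$verdicts %in% c("unidentifiable", "unobservable")
    expect_identical(unname(proj > 1e-6), unname(negative), info = spec[[1]])
  }
})

test_that("comparison flags constructed mismatches and tolerates empty input", {
  res <- list(EXP1 = classify(get_model("EXP1"), "V", seed = 1))
  res$EXP1$scenario <- "EXP1"
  ev <- expected_verdicts()
  cmp <- compare_catalogue(res, ev[ev$scenario == "EXP1", ])
  expect_equal(glance(cmp)$mismatches, 0L)

  # flip the expected verdict for lambda: exactly one mismatch
  ev2 <- ev[ev$scenario == "EXP1", ]
  ev2$expected[ev2$symbol == "lambda"] <- "unidentifiable"
  cmp2 <- compare_catalogue(res, ev2)
  expect_equal(glance(cmp2)$mismatches, 1L)

  # no results at all: everything skipped, nothing counted as a mismatch
  cmp3 <- compare_catalogue(list(), ev[ev$scenario %in% c("EXP1", "LOG"), ])
  expect_equal(glance(cmp3)$mismatches, 0L)
  expect_true(all(cmp3$status == "missing"))
})

test_that("results render to markdown, csv and json", {
  res <- list(EXP1 = classify(get_model("EXP1"), "V", seed = 1),
              LOG = classify(get_model("LOG"), "N", seed = 1))
  res$EXP1$scenario <- "EXP1"; res$LOG$scenario <- "LOG"

  md <- render_results(res, "markdown")
  expect_length(strsplit(md, "\n")[[1]], 2L + 2L) # header + rule + 2 data rows

  f <- withr::local_tempfile(fileext = ".csv")
  render_results(res, "csv", f)
  got <- utils::read.csv(f)
  expect_equal(nrow(got), 2L)
  expect_equal(got$scenario, c("EXP1", "LOG"))

  js <- render_results(res, "json")
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_length(parsed, 2L)
  expect_equal(parsed[[1]]$rank, 2L)
  expect_true(is.list(parsed[[1]]$verdicts))

  expect_error(render_results(res, "xml"))
})

test_that("tidy and glance expose results as tibbles", {
  res <- classify(get_model("LV"), "VS", seed = 1)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8L)
  expect_setequal(unique(td$role), c("state", "parameter"))
  gl <- glance(res)
  expect_equal(gl$rank, 7L)
  expect_false(gl$full)
  expect_equal(gl$n_identifiable, 3L)
})
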
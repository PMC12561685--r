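test_that("the catalogue ships exactly twenty models with the right inventories", {
  acr <- c("EXP1", "EXP2", "EXP3", "POW", "LV", "GOM1", "GOM2", "LOG", "BERT",
           "RAD1", "RAD2", "RCAP", "NECR", "CRS", "HCART", "IMRAD", "LEUK",
           "CYCLE", "CYTO2", "CICV")
  expect_length(acr, 20L)
  for (a in acr) expect_s3_class(get_model(a), "sio_model")
  expect_error(get_model("EXP9"), "valid acronyms")

  # symbol inventories per the model-feature table
  counts <- list(EXP1 = c(1, 1), EXP2 = c(1, 2), EXP3 = c(1, 3),
                 POW = c(1, 2), LV = c(2, 6), GOM2 = c(1, 2), LOG = c(1, 2),
                 BERT = c(1, 3), RAD1 = c(1, 4), RAD2 = c(1, 6),
                 RCAP = c(1, 3), NECR = c(2, 5), CRS = c(8, 23),
                 HCART = c(3, 9), LEUK = c(3, 10), CYCLE = c(4, 13),
                 CYTO2 = c(2, 2), CICV = c(2, 9))
  for (a in names(counts)) {
    m <- get_model(a)
    expect_equal(c(length(m$states), length(m$params)), counts[[a]],
                 info = a)
  }
  crs <- get_model("CRS")
  expect_setequal(crs$states, c("CI", "CE", "CP", "TP", "TN", "Mi", "Ma", "IL6"))
  rad1 <- get_model("RAD1")
  expect_setequal(rad1$params, c("lambda", "alpha", "beta", "d"))
  expect_equal(names(rad1$inputs), "u")
})

test_that("every model symbol belongs to exactly one declaration", {
  for (a in c("LV", "RAD2", "CRS", "CYCLE", "CICV", "IMRAD")) {
    m <- get_model(a)
    all_syms <- unique(unlist(lapply(c(m$dynamics, m$outputs), all.vars)))
    declared <- c(m$states, m$params, names(m$inputs), names(m$known_constants))
    expect_true(all(all_syms %in% declared), info = a)
    expect_false(anyDuplicated(c(m$states, m$params, names(m$inputs))) > 0,
                 info = a)
  }
})

test_that("the scenario list covers the analysed measurement configurations", {
  sc <- sio_scenarios()
  expect_gte(nrow(sc), 19L)
  expect_equal(sum(sc$acronym == "LV"), 3L)
  expect_equal(sum(sc$acronym == "CICV"), 2L)
  expect_equal(sum(sc$acronym == "NECR"), 2L)
  # every measured name resolves in its model's candidate outputs
  for (i in seq_len(nrow(sc))) {
    m <- get_model(sc$acronym[i])
    expect_true(all(sc$measured[[i]] %in% names(m$outputs)), info = sc$scenario[i])
  }
})

test_that("expected-verdict fixtures are disjoint and cover all symbols", {
  ev <- expected_verdicts()
  sc <- sio_scenarios()
  expect_setequal(unique(ev$scenario), sc$scenario)
  for (id in unique(ev$scenario)) {
    e <- ev[ev$scenario == id, ]
    m <- get_model(sc$acronym[sc$scenario == id])
    # asserted-or-ambiguous covers every state and parameter exactly once
    expect_setequal(e$symbol, c(m$states, m$params))
    expect_false(anyDuplicated(e$symbol) > 0, info = id)
    # asserted cells carry a verdict, ambiguous cells are excluded
    expect_true(all(!is.na(e$expected[!e$ambiguous])), info = id)
    # verdicts match roles
    pe <- e[e$role == "parameter" & !e$ambiguous, ]
    expect_true(all(pe$expected %in% c("identifiable", "unidentifiable")), info = id)
    se <- e[e$role == "state" & !e$ambiguous, ]
    expect_true(all(se$expected %in% c("observable", "unobservable")), info = id)
  }
  # the best-effort radio-immunotherapy encoding is flagged for exclusion
  expect_true(all(ev$skip_scenario[ev$scenario == "IMRAD_ca"]))
  expect_false(any(ev$skip_scenario[ev$scenario != "IMRAD_ca"]))
})

test_that("fixtures export as a summary CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_expected_csv(f)
  got <- utils::read.csv(f)
  expect_true(all(c("scenario", "identifiable", "unidentifiable",
                    "observable", "unobservable") %in% names(got)))
  expect_gte(nrow(got), 19L)
})
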
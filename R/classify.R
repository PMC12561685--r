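# Rank -> per-symbol verdicts via the column-removal test.

#' Classify identifiability and observability of a model
#'
#' Computes the generic rank of the saturated OI matrix. If it equals
#' `nx + ntheta`, every parameter is structurally locally identifiable and
#' every state observable. Otherwise each augmented symbol is tested by
#' removing its column and recomputing the rank: the symbol is
#' identifiable/observable iff the reduced rank drops below `r`. Rank
#' decisions are exact (prime-field evaluation at seeded generic points, best
#' of `trials`).
#'
#' @param model an `sio_model`.
#' @param measured character vector of measured output names (default: all
#'   candidate outputs of the model).
#' @param backend `"auto"` picks the symbolic Lie engine below
#'   `nx + ntheta < threshold` and the numeric jet engine otherwise;
#'   `"symbolic"` may refuse via the expression-swell guard, in which case
#'   `"auto"` falls back to numeric.
#' @param seed integer seed; verdicts are seed-stable for generic seeds.
#' @param trials number of evaluation points per rank decision.
#' @param threshold backend switch point on `nx + ntheta`.
#' @param term_budget symbolic per-entry term budget.
#' @return an object of class `sio_result`; see [tidy.sio_result()].
#' @export
classify <- function(model, measured = NULL, backend = c("auto", "symbolic", "numeric"),
                     seed = 1L, trials = 3L, threshold = 12L,
                     term_budget = 5e5) {
  backend <- match.arg(backend)
  measured <- resolve_measured(model, measured)
  naug <- n_aug(model)
  used <- backend
  if (backend == "auto") used <- if (naug < threshold) "symbolic" else "numeric"

  mats <- NULL
  order_used <- NA_integer_
  if (used == "symbolic") {
    oi <- tryCatch(
      saturated_oi(model, measured, seed = seed, trials = trials,
                   term_budget = term_budget),
      oncosio_swell = function(e) e)
    if (inherits(oi, "condition")) {
      if (backend == "symbolic") {
        stop("symbolic analysis refused (expression swell): ",
             conditionMessage(oi), "; use the numeric backend", call. = FALSE)
      }
      used <- "numeric"
    } else {
      mats <- Filter(Negate(is.null), attr(oi, "eval_rows"))
      order_used <- oi$order
    }
  }
  if (used == "numeric") {
    N <- naug - 1L
    mats <- lapply(seq_len(trials), function(i) {
      tryCatch(jet_oi_modp(model, measured, seed = seed + (i - 1L) * 101L, N = N),
               oncosio_pole = function(e) NULL)
    })
    mats <- Filter(Negate(is.null), mats)
    order_used <- N
  }
  if (length(mats) == 0L) {
    stop("sampling failure: all evaluation points rejected", call. = FALSE)
  }

  ranks <- vapply(mats, rank_modp, 0L)
  r <- max(ranks)
  full <- r == naug
  aug <- augmented_state(model)
  verdict <- rep(TRUE, naug)
  names(verdict) <- aug
  if (!full) {
    for (j in seq_len(naug)) {
      rr <- max(vapply(mats, function(M) rank_modp(M[, -j, drop = FALSE]), 0L))
      verdict[j] <- rr < r
    }
    # a directly measured state is observable by definition
    for (o in measured) {
      ex <- model$outputs[[o]]
      if (is.name(ex) && as.character(ex) %in% model$states) {
        verdict[[as.character(ex)]] <- TRUE
      }
    }
  }
  vlab <- ifelse(names(verdict) %in% model$states,
                 ifelse(verdict, "observable", "unobservable"),
                 ifelse(verdict, "identifiable", "unidentifiable"))
  names(vlab) <- names(verdict)
  structure(list(
    acronym = model$acronym,
    measured = measured,
    backend = used,
    rank = as.integer(r),
    n_aug = as.integer(naug),
    full = full,
    verdicts = vlab,
    states = model$states,
    params = model$params,
    order = as.integer(order_used),
    seed = as.integer(seed),
    trials = as.integer(trials)
  ), class = "sio_result")
}

#' @export
print.sio_result <- function(x, ...) {
  cat(sprintf("<sio_result %s | y = {%s}>  backend %s, rank %d / %d%s\n",
              x$acronym, paste(x$measured, collapse = ", "), x$backend,
              x$rank, x$n_aug, if (x$full) " (full)" else ""))
  if (!x$full) {
    vp <- x$verdicts[x$params]
    vs <- x$verdicts[x$states]
    cat("  identifiable:  ", paste(names(vp)[vp == "identifiable"], collapse = ", "), "\n")
    cat("  unidentifiable:", paste(names(vp)[vp == "unidentifiable"], collapse = ", "), "\n")
    cat("  observable:    ", paste(names(vs)[vs == "observable"], collapse = ", "), "\n")
    cat("  unobservable:  ", paste(names(vs)[vs == "unobservable"], collapse = ", "), "\n")
  } else {
    cat("  all parameters identifiable, all states observable\n")
  }
  invisible(x)
}

#' Run the SIO classification over the whole catalogue
#'
#' One result per catalogue measurement scenario (see [sio_scenarios()]).
#' Failures are collected per scenario, not fatal.
#'
#' @inheritParams classify
#' @param scenarios a scenario tibble, default [sio_scenarios()].
#' @return a list of `sio_result` (class `sio_catalogue`); failed scenarios
#'   carry the error condition instead.
#' @export
run_catalogue <- function(backend = "auto", seed = 1L, scenarios = sio_scenarios(),
                          threshold = 12L) {
  res <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    tryCatch({
      m <- get_model(sc$acronym)
      out <- classify(m, measured = sc$measured[[1L]], backend = backend,
                      seed = seed, threshold = threshold)
      out$scenario <- sc$scenario
      out
    }, error = function(e) {
      structure(list(scenario = sc$scenario, acronym = sc$acronym,
                     error = conditionMessage(e)), class = "sio_failure")
    })
  })
  names(res) <- scenarios$scenario
  class(res) <- "sio_catalogue"
  res
}

#' @export
print.sio_catalogue <- function(x, ...) {
  cat("<sio_catalogue> ", length(x), "scenarios\n")
  for (r in x) {
    if (inherits(r, "sio_failure")) {
      cat(sprintf("  %-10s FAILED: %s\n", r$scenario, r$error))
    } else {
      cat(sprintf("  %-10s rank %2d/%2d %s\n", r$scenario, r$rank, r$n_aug,
                  if (r$full) "full" else ""))
    }
  }
  invisible(x)
}

#' Compare classification results with the expected catalogue verdicts
#'
#' Cell-by-cell comparison of computed verdicts against the shipped expected
#' classifications, skipping each scenario's `ambiguous` symbols and the
#' best-effort IMRAD scenario.
#'
#' @param results an `sio_catalogue` (or list of `sio_result`).
#' @param expected tibble as [expected_verdicts()].
#' @return a tibble with one row per compared cell (class `sio_comparison`);
#'   `glance()` gives totals.
#' @export
compare_catalogue <- function(results, expected = expected_verdicts()) {
  rows <- list()
  for (i in seq_len(nrow(expected))) {
    e <- expected[i, ]
    res <- results[[e$scenario]]
    if (e$skip_scenario) next
    if (is.null(res) || inherits(res, "sio_failure")) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scenario = e$scenario, symbol = e$symbol, role = e$role,
        expected = e$expected, got = NA_character_,
        status = if (is.null(res)) "missing" else "failed")
      next
    }
    if (e$ambiguous) {
      status <- "skipped"
      got <- unname(res$verdicts[e$symbol])
    } else {
      got <- unname(res$verdicts[e$symbol])
      status <- if (identical(got, e$expected)) "match" else "mismatch"
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      scenario = e$scenario, symbol = e$symbol, role = e$role,
      expected = e$expected, got = got, status = status)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sio_comparison", class(out))
  out
}

#' Render classification results
#'
#' `markdown` mirrors the summary-table layout of the catalogue (known
#' inputs, identifiable/unidentifiable parameters, observable/unobservable
#' states, measured outputs); `csv` and `json` are machine-readable.
#'
#' @param results an `sio_catalogue` or list of `sio_result`.
#' @param format one of `"markdown"`, `"csv"`, `"json"`.
#' @param path optional output file.
#' @return the rendered text, invisibly if written to `path`.
#' @export
render_results <- function(results, format = c("markdown", "csv", "json"),
                           path = NULL) {
  format <- match.arg(format)
  ok <- Filter(function(r) inherits(r, "sio_result"), results)
  tab <- dplyr::bind_rows(lapply(ok, result_row))
  txt <- switch(format,
    markdown = {
      hdr <- paste("| Scenario | Known Inputs | Identifiable Parameters |",
                   "Unidentifiable Parameters | Observable States |",
                   "Unobservable States | Measured Outputs |")
      sep <- paste(c("|", rep(" --- |", 7L)), collapse = "")
      body <- apply(tab, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
      paste(c(hdr, sep, body), collapse = "\n")
    },
    csv = paste(utils::capture.output(utils::write.csv(tab, stdout(), row.names = FALSE)),
                collapse = "\n"),
    json = jsonlite::toJSON(lapply(ok, function(r) {
      list(scenario = r$scenario, acronym = r$acronym, measured = r$measured,
           backend = r$backend, rank = r$rank, n_aug = r$n_aug, full = r$full,
           verdicts = as.list(r$verdicts))
    }), auto_unbox = TRUE, pretty = TRUE)
  )
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

result_row <- function(r) {
  m <- get_model(r$acronym)
  vp <- r$verdicts[r$params]
  vs <- r$verdicts[r$states]
  fmt <- function(x) if (length(x) == 0L) "-" else paste(x, collapse = ", ")
  tibble::tibble(
    scenario = if (is.null(r$scenario)) r$acronym else r$scenario,
    known_inputs = fmt(names(m$inputs)),
    identifiable = fmt(names(vp)[vp == "identifiable"]),
    unidentifiable = fmt(names(vp)[vp == "unidentifiable"]),
    observable = fmt(names(vs)[vs == "observable"]),
    unobservable = fmt(names(vs)[vs == "unobservable"]),
    measured = paste(r$measured, collapse = ", ")
  )
}
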
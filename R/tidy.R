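# broom-style accessors

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a classification result
#'
#' One row per augmented symbol with its role and verdict.
#' @param x an `sio_result`.
#' @param ... unused.
#' @return a tibble with columns `acronym`, `symbol`, `role`, `verdict`,
#'   `positive` (identifiable/observable as logical).
#' @export
tidy.sio_result <- function(x, ...) {
  tibble::tibble(
    acronym = x$acronym,
    scenario = if (is.null(x$scenario)) NA_character_ else x$scenario,
    symbol = names(x$verdicts),
    role = ifelse(names(x$verdicts) %in% x$states, "state", "parameter"),
    verdict = unname(x$verdicts),
    positive = unname(x$verdicts) %in% c("identifiable", "observable")
  )
}

#' @rdname tidy.sio_result
#' @export
glance.sio_result <- function(x, ...) {
  tibble::tibble(
    acronym = x$acronym,
    scenario = if (is.null(x$scenario)) NA_character_ else x$scenario,
    measured = paste(x$measured, collapse = "+"),
    backend = x$backend,
    rank = x$rank,
    n_aug = x$n_aug,
    full = x$full,
    n_identifiable = sum(x$verdicts[x$params] == "identifiable"),
    n_observable = sum(x$verdicts[x$states] == "observable"),
    order = x$order,
    seed = x$seed
  )
}

#' @export
tidy.sio_catalogue <- function(x, ...) {
  ok <- Filter(function(r) inherits(r, "sio_result"), x)
  dplyr::bind_rows(lapply(ok, tidy))
}

#' @export
glance.sio_catalogue <- function(x, ...) {
  ok <- Filter(function(r) inherits(r, "sio_result"), x)
  dplyr::bind_rows(lapply(ok, glance))
}

#' @export
glance.sio_comparison <- function(x, ...) {
  tibble::tibble(
    cells = nrow(x),
    matches = sum(x$status == "match"),
    mismatches = sum(x$status == "mismatch"),
    skipped = sum(x$status %in% c("skipped", "missing", "failed"))
  )
}
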
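# Shared, lazily computed objects. The full catalogue run is the single most
# expensive computation in the suite; every test that needs classification
# results reuses this one run (seed 1, automatic backend choice).

.cache <- new.env(parent = emptyenv())

cached_catalogue <- function() {
  if (is.null(.cache$run)) .cache$run <- run_catalogue(backend = "auto", seed = 1)
  .cache$run
}

cached_comparison <- function() {
  if (is.null(.cache$cmp)) .cache$cmp <- compare_catalogue(cached_catalogue())
  .cache$cmp
}

scenario_result <- function(id) {
  res <- cached_catalogue()[[id]]
  stopifnot(inherits(res, "sio_result"))
  res
}
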
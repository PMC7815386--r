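# Programmatic fixtures, memoized so expensive datasets are built once per
# test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Reduced-size generator config for fast unit tests.
small_synth_config <- function(seed = 11, ...) {
  synth_config(
    n_per_class = c(Gansu = 10, Yunnan = 8, Qinghai = 8),
    n_points = 220,
    n_replicates = 2,
    seed = seed, ...)
}

small_dataset <- function() memo("small", generate_nir_dataset(small_synth_config()))

# Full-size dataset at the workflow's reference settings.
default_dataset <- function() memo("default", generate_nir_dataset(synth_config()))

default_averaged <- function() memo("default_avg", {
  ds <- default_dataset()
  j <- align_spectra(average_replicates(ds$spectra), ds$reference)
  j
})

toy_spectra <- function() {
  spectra_set(matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 2, 3, byrow = TRUE),
              c(9000, 6500, 4000), sample_id = c("a", "b"))
}
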
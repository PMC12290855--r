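# Shared fixtures: phantoms are generated in code, cached per session so
# several test files can reuse the expensive ones.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small, fast phantom: reduced grids and run length
small_config <- function(...) {
  phantom_config(n_subjects = 2L, n_volumes = 120L, n_segments = 4L,
                 cord_grid = c(4L, 4L, 16L), cortex_grid = c(16L, 7L, 2L),
                 ...)
}

small_phantom <- function() cached("small_phantom", {
  generate_phantom(small_config(), 1L)
})

# default-condition phantom (one subject) for recovery-style unit tests
default_phantom <- function() cached("default_phantom", {
  generate_phantom(phantom_config(), 1L)
})

# full default cohort + denoised series, reused by the acceptance tests
default_cohort_denoised <- function() cached("default_cohort_denoised", {
  cfg <- run_config(phantom_config(), stages = c("denoise", "seedfc",
                                                 "parcellation"))
  run_pipeline(cfg)
})

# nuisance design for one phantom subject (internal helper re-used in tests)
truth_design <- function(ph, organ) {
  cordmap:::phantom_design(ph, organ,
                           run_config(phantom_config()))
}
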
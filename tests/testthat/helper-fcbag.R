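# Shared builders for small test fixtures (all generated in code).

# Spectral frame directly from a complex coefficient matrix.
toy_frame <- function(C, frequency = 10, step_seconds = 0.02) {
  structure(C, frequency = frequency, step_seconds = step_seconds,
            times = (seq_len(ncol(C)) - 1) * step_seconds, srate = 250,
            class = "spectral_frame")
}

# Small desk-scale profile cohort configuration.
small_profile_config <- function(seed = 1, planted = NULL, ...) {
  sim_config(n_sources = 12, n_patients = 8, n_controls = 8,
             n_reference = 40, carrier_frequencies = c(8, 16, 32),
             n_generative = 5, planted_effect = planted, seed = seed, ...)
}

# Tiny time-series configuration (fast spectral + coupling runs).
small_ts_config <- function(seed = 1, n_sources = 4, duration = 30,
                            carrier_frequencies = 16, ...) {
  sim_config(n_sources = n_sources, n_patients = 2, n_controls = 2,
             n_reference = 3, duration = duration,
             carrier_frequencies = carrier_frequencies, seed = seed, ...)
}

expect_no_na <- function(x) expect_false(anyNA(x))

freq_label_test <- function(f) sprintf("f%.10g", f)
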
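# deterministic array: no noise, no drift
quiet_array <- function(drift_sd = 0) {
  arr <- default_array_config(drift_sd = drift_sd, noise_sd = 0)
  arr$ec$noise_sd <- 0
  arr$ph$noise_sd <- 0
  arr
}

# single-electrode spec used in hand-computed examples (nitrate working curve)
nitrate_spec <- function(...) {
  electrode_spec("NO3", -22.86, 208.47, noise_sd = 0, ...)
}

# tiny deterministic measurement record
toy_record <- function(conc = c(NO3 = 100, K = 50), seed = 11,
                       array = quiet_array()) {
  measure_msam(sample = solution_sample(conc), array = array, seed = seed)
}

# small seeded dataset for model tests (3-level design, 27 runs)
small_dataset <- function(seed = 3, array = default_array_config()) {
  build_dataset(design_spec(n_levels = 3, seed = seed), array = array)
}

expect_close <- function(object, expected, tol = 1e-9) {
  expect_true(max(abs(object - expected)) < tol,
              label = sprintf("max|diff| = %.3g", max(abs(object - expected))))
}
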
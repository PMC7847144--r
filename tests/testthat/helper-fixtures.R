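# Small generator configurations used across the suite. Desk-scale grids
# keep individual tests fast; the acceptance tests use the full defaults
# where the study conditions require them.

tiny_config <- function(seed = 1, ...) {
  sim_config(n_patients = 2, samples_per_patient = 1, grid = c(16, 16),
             seed = seed, ...)
}

# All stochastic terms off: heights are a deterministic function of tissue.
noiseless_config <- function(seed = 1, ...) {
  tiny_config(seed = seed, noise_sd = 0, detector_sd = 0, patient_sd = 0,
              spatial_sd = 0, mass_jitter_ppm = 0, ...)
}

# A hand-built 4-pixel dataset on a short axis, for I/O tests.
manual_dataset <- function() {
  mz <- seq(100, 110, by = 0.5)
  set.seed(42)
  intensity <- matrix(abs(rnorm(4 * length(mz), 10, 2)), 4, length(mz))
  msi_dataset(
    mz = mz, intensity = intensity,
    pixels = tibble::tibble(
      sample_id = "s1", x = c(0L, 1L, 0L, 1L), y = c(0L, 0L, 1L, 1L),
      patient_id = "p1",
      tissue_label = c("NCE", "stroma", "cancer", "matrix")
    ),
    polarity = "negative"
  )
}

# Gaussian peak on an arbitrary baseline, as a single spectrum.
gaussian_spectrum <- function(center = 105, height = 50, sigma = 0.3,
                              baseline = 0, noise_sd = 0, seed = 7,
                              mz = seq(100, 110, by = 0.02)) {
  set.seed(seed)
  y <- baseline + height * exp(-(mz - center)^2 / (2 * sigma^2)) +
    (if (noise_sd > 0) rnorm(length(mz), 0, noise_sd) else 0)
  msi_spectrum(mz, pmax(y, 0))
}

expect_ppm <- function(mz_found, mz_true, tol_ppm) {
  expect_lt(1e6 * abs(mz_found - mz_true) / mz_true, tol_ppm)
}
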
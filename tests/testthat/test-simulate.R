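test_that("tissue maps honour proportions, margin, and determinism", {
  expect_error(
    generate_tissue_map(16, 16, c(NCE = 0.5, stroma = 0.4, cancer = 0.2),
                        2, 1),
    "sum to 1"
  )

  m1 <- generate_tissue_map(16, 16, c(NCE = 1, stroma = 0, cancer = 0), 2, 5)
  interior <- m1[3:14, 3:14]
  expect_true(all(interior == "NCE"))
  expect_true(all(m1[1:2, ] == "matrix"))
  expect_true(all(m1[, 15:16] == "matrix"))

  m2 <- generate_tissue_map(16, 16, c(NCE = 0.2, stroma = 0.5, cancer = 0.3),
                            2, 9)
  m3 <- generate_tissue_map(16, 16, c(NCE = 0.2, stroma = 0.5, cancer = 0.3),
                            2, 9)
  expect_identical(m2, m3)

  props <- c(NCE = 0.25, stroma = 0.45, cancer = 0.30)
  m4 <- generate_tissue_map(64, 64, props, 4, 3)
  inner <- m4[3:62, 3:62]
  frac <- table(inner) / length(inner)
  for (lb in names(props)) {
    expect_lt(abs(frac[[lb]] - props[[lb]]), 0.10)
  }
})

test_that("noiseless spectra reproduce the closed-form apex heights", {
  cfg <- noiseless_config(baseline_params = c(0, 120))
  panel <- cfg$peak_panel
  sp <- spectrum_from_truth(cfg, "cancer", patient_intercept = 0.3)
  for (j in c(1, 2, 15, 30)) {
    expected <- 2^(panel$base_log2[j] + panel$effect_cancer[j] + 0.3)
    apex <- max(sp$intensity[abs(sp$mz - panel$mz[j]) < 0.3])
    expect_lt(abs(apex - expected) / expected, 0.01)
  }
})

test_that("matrix-label pixels carry only matrix peaks and baseline", {
  cfg <- noiseless_config()
  sp <- spectrum_from_truth(cfg, "matrix")
  panel <- cfg$peak_panel
  baseline_at <- function(mz) {
    cfg$baseline_params[[1]] * exp(-(mz - cfg$mz_range[1]) /
                                     cfg$baseline_params[[2]])
  }
  for (j in seq_len(nrow(panel))) {
    h <- max(sp$intensity[abs(sp$mz - panel$mz[j]) < 0.2])
    expect_lt(h, baseline_at(panel$mz[j]) + 1)
  }
  # matrix peaks themselves are present
  mp <- cfg$matrix_peaks
  expect_gt(max(sp$intensity[abs(sp$mz - mp$mz[1]) < 0.2]), mp$intensity[1] / 2)
})

test_that("isotope envelopes render at the configured relative abundance", {
  panel <- default_panel()[1, ]
  panel$iso2 <- 0.3
  cfg <- noiseless_config(peak_panel = panel, baseline_params = c(0, 120))
  sp <- spectrum_from_truth(cfg, "NCE")
  apex <- max(sp$intensity[abs(sp$mz - panel$mz) < 0.3])
  iso <- max(sp$intensity[abs(sp$mz - (panel$mz + 1.00335)) < 0.3])
  expect_lt(abs(iso / apex - 0.3), 0.02)
})

test_that("generation is fully reproducible from the seed", {
  cfg <- sim_config(n_patients = 2, samples_per_patient = 1, grid = c(10, 10),
                    seed = 13)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$truth$effect_table, b$truth$effect_table)
  expect_identical(a$truth$patient_intercepts, b$truth$patient_intercepts)
  expect_identical(a$truth$tissue_maps, b$truth$tissue_maps)
  expect_identical(a$dataset$intensity, b$dataset$intensity)
})

test_that("with all noise off, empirical log2FC matches the effect table", {
  cfg <- noiseless_config(seed = 5)
  gen <- generate_dataset(cfg)
  ds <- tic_normalize(gen$dataset)
  panel <- cfg$peak_panel
  pl <- msi_peaklist(tibble::tibble(mz = panel$mz, height = 1, snr = 10,
                                    source_tissue = "cancer"))
  pm <- extract_peak_matrix(ds, pl, 150)
  et <- gen$truth$effect_table
  for (pr in list(c("cancer", "NCE"), c("cancer", "stroma"),
                  c("stroma", "NCE"))) {
    lfc <- log2fc(pm, pr)
    truth <- et$log2fc_true[et$pair == paste0(pr[1], "_vs_", pr[2])]
    expect_lt(max(abs(lfc$log2fc - truth)), 0.01)
  }
})

test_that("realized patient intercept spread reflects the configured SD", {
  cfg <- sim_config(n_patients = 6, samples_per_patient = 1, grid = c(8, 8),
                    patient_sd = 0.5, seed = 21)
  truth <- generate_dataset(cfg)$truth
  sds <- truth$patient_intercepts |>
    dplyr::group_by(mz) |>
    dplyr::summarise(s = sd(intercept))
  expect_gt(mean(sds$s), 0.1)
  expect_lt(mean(sds$s), 1.2)
})

test_that("spatial correlation length increases neighbour correlation monotonically", {
  neighbour_cor <- function(corr_length, seed) {
    set.seed(seed)
    cors <- replicate(30, {
      f <- msidiff:::smooth_field(matrix(rnorm(32 * 32), 32, 32), corr_length)
      cor(as.vector(f[-32, ]), as.vector(f[-1, ]))
    })
    mean(cors)
  }
  c0 <- neighbour_cor(0, 1)
  c2 <- neighbour_cor(2, 1)
  c8 <- neighbour_cor(8, 1)
  expect_lt(c0, c2)
  expect_lt(c2, c8)
})

test_that("the direct peak-matrix simulator matches the rendered pipeline statistically", {
  cfg <- sim_config(n_patients = 3, samples_per_patient = 1, grid = c(20, 20),
                    seed = 31)
  fast <- simulate_peak_matrix(cfg)
  expect_s3_class(fast$peak_matrix, "msi_peakmatrix")
  expect_false(any(fast$peak_matrix$row_meta$tissue_label == "matrix"))
  expect_equal(ncol(fast$peak_matrix$values), nrow(cfg$peak_panel))
  # group-mean log2 ratios agree with the planted effects
  lfc <- log2fc(fast$peak_matrix, c("cancer", "NCE"))
  planted <- cfg$peak_panel$effect_cancer
  expect_lt(median(abs(lfc$log2fc - planted)), 0.2)
  # deterministic
  fast2 <- simulate_peak_matrix(cfg)
  expect_identical(fast$peak_matrix$values, fast2$peak_matrix$values)
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(grid = c(3, 10)), ">= 4")
  expect_error(sim_config(patient_sd = -1), "SD")
  expect_error(sim_config(proportions = c(NCE = 0.5, stroma = 0.5,
                                          cancer = 0.5)), "sum to 1")
  bad_panel <- default_panel()
  bad_panel$iso2[1] <- 1.5
  expect_error(sim_config(peak_panel = bad_panel), "Isotope")
})

test_that("ground truth writes as plain-text tables", {
  cfg <- sim_config(n_patients = 1, samples_per_patient = 1, grid = c(8, 8),
                    seed = 2)
  truth <- generate_dataset(cfg)$truth
  dir <- file.path(withr::local_tempdir(), "truth")
  write_truth(truth, dir)
  expect_true(file.exists(file.path(dir, "effects.tsv")))
  expect_true(file.exists(file.path(dir, "patients.tsv")))
  eff <- readr::read_tsv(file.path(dir, "effects.tsv"),
                         show_col_types = FALSE)
  expect_equal(nrow(eff), 3 * nrow(cfg$peak_panel))
})
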
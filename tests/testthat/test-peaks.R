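test_that("peak picking finds injected peaks and respects thresholds", {
  mz <- seq(100, 110, by = 0.02)
  flat <- msi_spectrum(mz, rep(1, length(mz)))
  expect_equal(nrow(pick_peaks(flat, abs_threshold = 0.1)), 0)

  pk <- gaussian_spectrum(center = 104.57, height = 30, sigma = 0.08,
                          noise_sd = 1, seed = 3)
  found <- pick_peaks(pk, snr_min = 2, abs_threshold = 5)
  main <- found[which.max(found$height), ]
  expect_lt(abs(main$mz - 104.57), 0.02)
  expect_gt(main$snr, 2)

  weak <- gaussian_spectrum(center = 105, height = 3, sigma = 0.08)
  expect_equal(nrow(pick_peaks(weak, snr_min = 0, abs_threshold = 5)), 0)
})

test_that("deisotoping removes +k*1.00335 satellites of stronger peaks", {
  pl <- msi_peaklist(tibble::tibble(
    mz = c(500.000, 501.0034), height = c(1.0, 0.3), snr = c(10, 4),
    source_tissue = "cancer"
  ))
  out <- deisotope(pl, iso_tol_ppm = 50)
  expect_equal(out$mz, 500.000)

  single <- msi_peaklist(tibble::tibble(mz = 500, height = 1, snr = 5,
                                        source_tissue = "NCE"))
  expect_equal(nrow(deisotope(single)), 1)

  non_iso <- msi_peaklist(tibble::tibble(
    mz = c(500.0, 500.5), height = c(1.0, 0.3), snr = c(10, 4),
    source_tissue = "NCE"
  ))
  expect_equal(nrow(deisotope(non_iso, 50)), 2)
})

test_that("merging pools lists, removes duplicates, and keeps minimum spacing", {
  base <- msi_peaklist(tibble::tibble(
    mz = c(400.1, 450.2, 500.3), height = c(1, 2, 3), snr = c(5, 5, 5),
    source_tissue = "NCE"
  ))
  triple <- merge_peaklists(list(base, base, base), window_ppm = 150)
  expect_equal(nrow(triple), 3)

  shifted <- base
  shifted$mz <- shifted$mz + 5
  disjoint <- merge_peaklists(list(base, shifted), window_ppm = 150)
  expect_equal(nrow(disjoint), 6)

  # brute-force single-linkage oracle on random lists
  oracle_count <- function(mz, tol_ppm) {
    mz <- sort(mz)
    sum(diff(mz) > tol_ppm * mz[-1] / 1e6) + 1
  }
  set.seed(11)
  for (rep in 1:20) {
    mzs <- sort(runif(40, 400, 700))
    lists <- split(mzs, rep_len(1:3, length(mzs)))
    pls <- lapply(lists, function(m) {
      msi_peaklist(tibble::tibble(mz = m, height = runif(length(m)),
                                  snr = 5, source_tissue = "NCE"))
    })
    merged <- merge_peaklists(pls, window_ppm = 200)
    expect_equal(nrow(merged), oracle_count(mzs, 200))
    gaps_ppm <- diff(merged$mz) / merged$mz[-1] * 1e6
    expect_true(all(gaps_ppm > 200))
  }
})

test_that("peak-height extraction takes the window maximum", {
  ds <- manual_dataset()
  ds <- tic_normalize(ds)
  pl <- msi_peaklist(tibble::tibble(mz = c(102, 108), height = 1, snr = 5,
                                    source_tissue = "NCE"))
  pm <- extract_peak_matrix(ds, pl, window_ppm = 10000)
  # annotated non-matrix rows only
  expect_equal(nrow(pm$values), 3)
  i <- 1
  for (j in 1:2) {
    half <- pl$mz[j] * 10000 / 2e6
    cols <- which(ds$mz >= pl$mz[j] - half & ds$mz <= pl$mz[j] + half)
    expect_equal(unname(pm$values[i, j]), max(ds$intensity[i, cols]))
  }

  # zero signal in the window yields zero
  zero_ds <- ds
  zero_ds$intensity[, abs(ds$mz - 102) < 0.6] <- 0
  pm0 <- extract_peak_matrix(zero_ds, pl, window_ppm = 10000)
  expect_true(all(pm0$values[, 1] == 0))

  close_pl <- msi_peaklist(tibble::tibble(mz = c(102, 102.0005), height = 1,
                                          snr = 5, source_tissue = "NCE"))
  expect_error(extract_peak_matrix(ds, close_pl, window_ppm = 10000),
               "Overlapping")
})

test_that("extraction is equivariant under row permutation", {
  cfg <- tiny_config(seed = 15)
  ds <- tic_normalize(generate_dataset(cfg)$dataset)
  pl <- msi_peaklist(tibble::tibble(mz = cfg$peak_panel$mz, height = 1,
                                    snr = 5, source_tissue = "NCE"))
  pm <- extract_peak_matrix(ds, pl, 150)
  set.seed(1)
  perm <- sample(n_spectra(ds))
  ds2 <- subset_pixels(ds, perm)
  pm2 <- extract_peak_matrix(ds2, pl, 150)
  key <- function(m) paste(m$row_meta$sample_id, m$row_meta$x, m$row_meta$y)
  expect_equal(pm2$values[order(key(pm2)), ], pm$values[order(key(pm)), ])
})

test_that("exclusion masses are dropped from a peak list", {
  pl <- msi_peaklist(tibble::tibble(mz = c(400.1, 450.2, 500.3),
                                    height = 1, snr = 5,
                                    source_tissue = "NCE"))
  out <- exclude_masses(pl, 450.2, tol_ppm = 50)
  expect_equal(out$mz, c(400.1, 500.3))
})

test_that("mass jitter within the window keeps extracted heights near the true apex", {
  base_args <- list(seed = 17, noise_sd = 0, detector_sd = 0, patient_sd = 0,
                    spatial_sd = 0)
  cfg_j <- do.call(tiny_config, c(base_args, mass_jitter_ppm = 10))
  cfg_0 <- do.call(tiny_config, c(base_args, mass_jitter_ppm = 0))
  ds_j <- tic_normalize(generate_dataset(cfg_j)$dataset)
  ds_0 <- tic_normalize(generate_dataset(cfg_0)$dataset)
  pl <- msi_peaklist(tibble::tibble(mz = cfg_j$peak_panel$mz, height = 1,
                                    snr = 5, source_tissue = "NCE"))
  pm_j <- extract_peak_matrix(ds_j, pl, 150)
  pm_0 <- extract_peak_matrix(ds_0, pl, 150)
  rel <- abs(pm_j$values / pm_0$values - 1)
  expect_gte(mean(rel < 0.05), 0.99)
})
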
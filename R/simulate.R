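#' Default synthetic peak panel
#'
#' Thirty metabolite-like masses between m/z 450 and 595. Eight masses carry
#' cancer-vs-NCE effects of +-0.8 on the log2 scale (four up, four down,
#' magnitudes near the citrate/choline range of prostate MSI studies) and
#' four masses carry stroma-specific effects of +0.5. Every peak has a
#' two-isotope envelope at +1.00335 and +2.0067 Da.
#'
#' @return a tibble with columns `mz`, `base_log2`, `effect_stroma`,
#'   `effect_cancer`, `iso2`, `iso3`, `sigma`.
#' @export
default_panel <- function() {
  n <- 30
  mz <- seq(450.17, 595.17, length.out = n)
  base_log2 <- 11 + 1.2 * sin(seq(0, 3 * pi, length.out = n))
  effect_cancer <- numeric(n)
  effect_stroma <- numeric(n)
  cancer_idx <- c(2, 5, 8, 11, 14, 17, 20, 23)
  effect_cancer[cancer_idx] <- rep(c(0.8, -0.8), 4)
  stroma_idx <- c(3, 9, 15, 21)
  effect_stroma[stroma_idx] <- 0.5
  tibble(
    mz = mz, base_log2 = base_log2,
    effect_stroma = effect_stroma, effect_cancer = effect_cancer,
    iso2 = 0.35, iso3 = 0.08, sigma = 0.08
  )
}

#' Default matrix (chemical background) peaks
#'
#' Five peaks present in every pixel, including the matrix-only margin,
#' placed away from the panel masses and their isotopes.
#'
#' @return a tibble with columns `mz`, `intensity`, `iso2`, `sigma`.
#' @export
default_matrix_peaks <- function() {
  # intense relative to the tissue panel: matrix signal dominates the TIC,
  # as in real MALDI acquisitions, so tissue effects barely perturb the TIC
  tibble(
    mz = c(443.47, 463.47, 483.47, 523.47, 583.47),
    intensity = c(200000, 150000, 172000, 120000, 97000),
    iso2 = 0.3, sigma = 0.08
  )
}

#' Generator configuration
#'
#' Defines the conditions the synthetic MSI generator emulates: a multi-patient
#' study with per-patient tissue sections, tissue-type fixed effects on the
#' log2 scale, patient-level random intercepts (drawn per patient and mass),
#' spatially autocorrelated residual variation, isotope envelopes, ubiquitous
#' matrix peaks with a matrix-only margin, exponential baseline drift, additive
#' detector noise, and a small per-spectrum linear mass-scale error.
#'
#' @param n_patients number of patients.
#' @param samples_per_patient tissue sections per patient.
#' @param grid `c(width, height)` in pixels; a fixed 2-pixel outer margin is
#'   always matrix-only.
#' @param proportions named interior fractions for `NCE`, `stroma`, `cancer`;
#'   must sum to 1.
#' @param mz_range m/z interval (Da) of the shared axis.
#' @param axis_step axis spacing (Da).
#' @param peak_panel tibble as returned by [default_panel()].
#' @param matrix_peaks tibble as returned by [default_matrix_peaks()].
#' @param patient_sd SD of patient random intercepts (log2 scale), drawn
#'   independently per patient and mass.
#' @param spatial_sd SD of the spatially autocorrelated residual (log2 scale).
#' @param spatial_corr_length correlation length of the residual field in
#'   pixels (Gaussian-kernel smoothing bandwidth).
#' @param noise_sd SD of i.i.d. per-peak noise (log2 scale).
#' @param detector_sd SD of additive detector noise per axis point
#'   (intensity units).
#' @param baseline_params `c(amplitude, decay)` of the exponential baseline
#'   `amplitude * exp(-(mz - mz_min)/decay)`.
#' @param mass_jitter_ppm SD of the per-spectrum linear mass-scale error
#'   (ppm), truncated at +-3 SD so the worst-case shift is bounded.
#' @param polarity ion mode of the simulated acquisition.
#' @param seed root seed; all generator randomness derives from it.
#' @return an object of class `msi_sim_config`.
#' @export
sim_config <- function(n_patients = 6,
                       samples_per_patient = 3,
                       grid = c(40, 40),
                       proportions = c(NCE = 0.21, stroma = 0.44, cancer = 0.35),
                       mz_range = c(440, 600),
                       axis_step = 0.03,
                       peak_panel = default_panel(),
                       matrix_peaks = default_matrix_peaks(),
                       patient_sd = 0.5,
                       spatial_sd = 0.3,
                       spatial_corr_length = 4,
                       noise_sd = 0.45,
                       detector_sd = 2,
                       baseline_params = c(amplitude = 5, decay = 120),
                       mass_jitter_ppm = 10,
                       polarity = "positive",
                       seed = 1) {
  if (any(grid < 4)) abort("Grid dimensions must be >= 4.")
  sds <- c(patient_sd, spatial_sd, noise_sd, detector_sd, mass_jitter_ppm)
  if (any(sds < 0)) abort("All SDs must be >= 0.")
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("Tissue proportions must sum to 1.")
  }
  if (!all(c("NCE", "stroma", "cancer") %in% names(proportions))) {
    abort("`proportions` must be named NCE, stroma, cancer.")
  }
  if (any(peak_panel$iso2 <= 0 | peak_panel$iso2 > 1) ||
      any(peak_panel$iso3 <= 0 | peak_panel$iso3 > 1)) {
    abort("Isotope abundances must lie in (0, 1].")
  }
  if (any(peak_panel$mz < mz_range[1] | peak_panel$mz > mz_range[2])) {
    abort("All panel masses must lie inside `mz_range`.")
  }
  structure(
    list(
      n_patients = n_patients, samples_per_patient = samples_per_patient,
      grid = as.integer(grid), margin = 2L, proportions = proportions,
      mz_range = mz_range, axis_step = axis_step,
      peak_panel = peak_panel, matrix_peaks = matrix_peaks,
      patient_sd = patient_sd, spatial_sd = spatial_sd,
      spatial_corr_length = spatial_corr_length,
      noise_sd = noise_sd, detector_sd = detector_sd,
      baseline_params = baseline_params,
      mass_jitter_ppm = mass_jitter_ppm,
      polarity = match.arg(polarity, c("positive", "negative")),
      seed = as.integer(seed)
    ),
    class = "msi_sim_config"
  )
}

#' Smooth a matrix with a separable Gaussian kernel
#' @noRd
smooth_field <- function(mat, corr_length) {
  if (corr_length <= 0) return(mat)
  kern1d <- function(n) {
    k <- outer(seq_len(n), seq_len(n), function(i, j) {
      exp(-(i - j)^2 / (2 * corr_length^2))
    })
    k / rowSums(k)
  }
  kr <- kern1d(nrow(mat))
  kc <- kern1d(ncol(mat))
  kr %*% mat %*% t(kc)
}

#' Generate a blobby tissue-label map
#'
#' Thresholds a Gaussian-smoothed random field at the rank cutoffs implied by
#' the requested proportions, so realized interior fractions match the request
#' up to rounding. A fixed 2-pixel outer margin is always matrix-only,
#' mirroring the separate matrix regions recorded in MSI experiments.
#'
#' @param width,height grid size in pixels.
#' @param proportions named fractions for `NCE`, `stroma`, `cancer`
#'   (summing to 1).
#' @param corr_length smoothing bandwidth in pixels (0 = independent pixels).
#' @param seed integer seed.
#' @return a `height x width` character matrix of labels; entry `[y+1, x+1]`
#'   is the label of pixel `(x, y)`.
#' @export
generate_tissue_map <- function(width, height, proportions, corr_length,
                                seed) {
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("Tissue proportions must sum to 1.")
  }
  margin <- 2L
  iw <- width - 2L * margin
  ih <- height - 2L * margin
  if (iw < 1 || ih < 1) abort("Grid too small for the matrix margin.")
  field <- with_seed(seed, {
    smooth_field(matrix(rnorm(ih * iw), ih, iw), corr_length)
  })
  n <- length(field)
  p <- proportions[c("NCE", "stroma", "cancer")]
  n1 <- round(p[[1]] * n)
  n2 <- round(p[[2]] * n)
  lab <- character(n)
  ord <- order(field)
  lab[ord[seq_len(n1)]] <- "NCE"
  lab[ord[seq_len(n2) + n1]] <- "stroma"
  lab[ord[seq(n1 + n2 + 1, length.out = n - n1 - n2)]] <- "cancer"
  interior <- matrix(lab, ih, iw)
  full <- matrix("matrix", height, width)
  full[(margin + 1):(height - margin), (margin + 1):(width - margin)] <-
    interior
  full
}

#' Shared m/z axis of a generator configuration
#' @param config an `msi_sim_config`.
#' @export
sim_axis <- function(config) {
  seq(config$mz_range[1], config$mz_range[2], by = config$axis_step)
}

#' @noRd
sim_baseline <- function(config, axis) {
  a <- config$baseline_params[[1]]
  d <- config$baseline_params[[2]]
  a * exp(-(axis - axis[1]) / d)
}

# Add a Gaussian profile to `vec` (uniform axis; arithmetic window lookup).
#' @noRd
add_gaussian <- function(vec, axis0, step, n, center, height, sigma) {
  lo <- max(1L, as.integer(ceiling((center - 4 * sigma - axis0) / step)) + 1L)
  hi <- min(n, as.integer(floor((center + 4 * sigma - axis0) / step)) + 1L)
  if (hi < lo) return(vec)
  idx <- lo:hi
  mzi <- axis0 + (idx - 1L) * step
  vec[idx] <- vec[idx] + height * exp(-(mzi - center)^2 / (2 * sigma^2))
  vec
}

#' Render one pixel spectrum from ground truth
#'
#' The expected log2 apex height of each panel mass is
#' `base + tissue_effect + patient_intercept + spatial_residual`, with i.i.d.
#' per-peak noise of SD `noise_sd` added on the log2 scale. Heights are
#' rendered as Gaussian profiles with the panel's `sigma`, plus isotope peaks
#' at `+k * 1.00335` Da scaled by the envelope, plus the ubiquitous matrix
#' peaks, plus the exponential baseline and additive detector noise. The
#' spectrum's ppm jitter shifts every peak centre by a linear mass-scale
#' factor (equivalent to warping the axis while keeping continuous-mode
#' storage). Matrix-labelled pixels contain matrix peaks, baseline, and noise
#' only.
#'
#' Consumes random numbers from the current RNG stream.
#'
#' @param config an `msi_sim_config`.
#' @param tissue_label pixel label.
#' @param patient_intercept scalar or per-mass vector of patient intercepts
#'   (log2 scale).
#' @param spatial_residual scalar or per-mass vector of spatial residuals
#'   (log2 scale).
#' @param jitter_ppm this spectrum's linear mass-scale error in ppm.
#' @return an [msi_spectrum].
#' @export
spectrum_from_truth <- function(config, tissue_label, patient_intercept = 0,
                                spatial_residual = 0, jitter_ppm = 0) {
  tissue_label <- match.arg(tissue_label, TISSUE_LABELS)
  axis <- sim_axis(config)
  vec <- render_intensities(
    config, axis, sim_baseline(config, axis), tissue_label,
    patient_intercept, spatial_residual, jitter_ppm
  )
  msi_spectrum(axis, vec, tissue_label = tissue_label,
               polarity = config$polarity)
}

#' @noRd
render_intensities <- function(config, axis, baseline, tissue_label,
                               patient_intercept, spatial_residual,
                               jitter_ppm) {
  vec <- baseline
  axis0 <- axis[1]
  step <- config$axis_step
  n <- length(axis)
  warp <- 1 + jitter_ppm * 1e-6
  panel <- config$peak_panel
  if (tissue_label != "matrix") {
    eff <- switch(tissue_label,
      NCE = 0, unannotated = 0,
      stroma = panel$effect_stroma,
      cancer = panel$effect_cancer
    )
    log2h <- panel$base_log2 + eff +
      rep_len(patient_intercept, nrow(panel)) +
      rep_len(spatial_residual, nrow(panel)) +
      (if (config$noise_sd > 0) rnorm(nrow(panel), 0, config$noise_sd) else 0)
    h <- 2^log2h
    for (j in seq_len(nrow(panel))) {
      envelope <- c(1, panel$iso2[j], panel$iso3[j])
      for (k in 0:2) {
        vec <- add_gaussian(
          vec, axis0, step, n, (panel$mz[j] + k * ISOTOPE_DA) * warp,
          h[j] * envelope[k + 1], panel$sigma[j]
        )
      }
    }
  }
  mp <- config$matrix_peaks
  mh <- mp$intensity *
    (if (config$noise_sd > 0) 2^rnorm(nrow(mp), 0, config$noise_sd) else 1)
  for (j in seq_len(nrow(mp))) {
    for (k in 0:1) {
      vec <- add_gaussian(
        vec, axis0, step, n, (mp$mz[j] + k * ISOTOPE_DA) * warp,
        mh[j] * c(1, mp$iso2[j])[k + 1], mp$sigma[j]
      )
    }
  }
  if (config$detector_sd > 0) {
    vec <- vec + rnorm(length(vec), 0, config$detector_sd)
  }
  pmax(vec, 0)
}

#' @noRd
sim_patient_ids <- function(config) sprintf("p%02d", seq_len(config$n_patients))

# Batch renderer for one sample: same intensity model as
# render_intensities, vectorized across pixels per peak. Consumes RNG draws
# (per-peak noise, matrix-peak noise, detector noise).
#' @noRd
render_sample_rows <- function(config, axis, baseline, labs, u_row,
                               spat_mat, jit) {
  n_px <- length(labs)
  n_axis <- length(axis)
  step <- config$axis_step
  panel <- config$peak_panel
  nm <- nrow(panel)
  mp <- config$matrix_peaks
  nmp <- nrow(mp)
  is_tissue <- labs != "matrix"

  # per-pixel linear heights for every panel mass (zero on matrix pixels)
  eff_mat <- matrix(0, n_px, nm)
  eff_mat[labs == "stroma", ] <- matrix(panel$effect_stroma,
                                        sum(labs == "stroma"), nm,
                                        byrow = TRUE)
  eff_mat[labs == "cancer", ] <- matrix(panel$effect_cancer,
                                        sum(labs == "cancer"), nm,
                                        byrow = TRUE)
  log2h <- matrix(panel$base_log2 + u_row, n_px, nm, byrow = TRUE) +
    eff_mat + spat_mat
  if (config$noise_sd > 0) {
    log2h <- log2h + matrix(rnorm(n_px * nm, 0, config$noise_sd), n_px, nm)
  }
  h_mat <- 2^log2h * is_tissue
  m_mat <- matrix(mp$intensity, n_px, nmp, byrow = TRUE)
  if (config$noise_sd > 0) {
    m_mat <- m_mat * 2^matrix(rnorm(n_px * nmp, 0, config$noise_sd),
                              n_px, nmp)
  }

  warp <- 1 + jit * 1e-6
  rows <- t(matrix(baseline, n_axis, n_px))
  # one vectorized accumulation per (peak, isotope) over all pixels at once
  splat <- function(mz0, heights, sigma) {
    centers <- mz0 * warp
    lo <- max(1L, as.integer(ceiling((min(centers) - 4 * sigma - axis[1]) /
                                       step)) + 1L)
    hi <- min(n_axis, as.integer(floor((max(centers) + 4 * sigma - axis[1]) /
                                         step)) + 1L)
    if (hi < lo) return(invisible())
    idx <- lo:hi
    delta <- outer(centers, axis[idx], "-")
    rows[, idx] <<- rows[, idx] + heights * exp(-delta^2 / (2 * sigma^2))
    invisible()
  }
  for (j in seq_len(nm)) {
    splat(panel$mz[j], h_mat[, j], panel$sigma[j])
    splat(panel$mz[j] + ISOTOPE_DA, h_mat[, j] * panel$iso2[j],
          panel$sigma[j])
    splat(panel$mz[j] + 2 * ISOTOPE_DA, h_mat[, j] * panel$iso3[j],
          panel$sigma[j])
  }
  for (j in seq_len(nmp)) {
    splat(mp$mz[j], m_mat[, j], mp$sigma[j])
    splat(mp$mz[j] + ISOTOPE_DA, m_mat[, j] * mp$iso2[j], mp$sigma[j])
  }
  if (config$detector_sd > 0) {
    rows <- rows + rnorm(length(rows), 0, config$detector_sd)
  }
  rows[rows < 0] <- 0
  rows
}

#' Generate a full synthetic MSI dataset with ground truth
#'
#' Produces `n_patients * samples_per_patient` tissue sections. Patient
#' intercepts are drawn once per patient (independently per panel mass);
#' each sample receives its own tissue map and per-mass spatially
#' autocorrelated residual fields (Gaussian-smoothed white noise,
#' standardized to unit variance and scaled by `spatial_sd`). Fully
#' reproducible from `config$seed`.
#'
#' @param config an `msi_sim_config`.
#' @return a list with elements `dataset` (an annotated [msi_dataset]) and
#'   `truth` (class `msi_sim_truth`: per-sample tissue maps, the true
#'   per-pair log2 fold-change table, patient intercepts, and the seed).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "msi_sim_config"))
  axis <- sim_axis(config)
  baseline <- sim_baseline(config, axis)
  panel <- config$peak_panel
  nm <- nrow(panel)
  w <- config$grid[1]; h <- config$grid[2]
  patients <- sim_patient_ids(config)
  n_samples <- config$n_patients * config$samples_per_patient

  u <- with_seed(derive_seed(config$seed, "patient_intercepts"), {
    matrix(rnorm(config$n_patients * nm, 0, config$patient_sd),
           config$n_patients, nm, dimnames = list(patients, NULL))
  })

  n_px_sample <- w * h
  n_total <- n_samples * n_px_sample
  intensity <- matrix(0, n_total, length(axis))
  sample_ids <- character(n_total)
  patient_ids <- character(n_total)
  xs <- ys <- integer(n_total)
  labels <- character(n_total)
  tissue_maps <- vector("list", n_samples)
  map_names <- character(n_samples)

  row <- 0L
  s_idx <- 0L
  for (p in seq_len(config$n_patients)) {
    for (s in seq_len(config$samples_per_patient)) {
      s_idx <- s_idx + 1L
      sid <- sprintf("s%02d_%s", s, patients[p])
      map_names[s_idx] <- sid
      map_seed <- derive_seed(config$seed, paste0("map_", sid))
      tmap <- generate_tissue_map(w, h, config$proportions,
                                  config$spatial_corr_length, map_seed)
      tissue_maps[[s_idx]] <- tmap

      sample_work <- with_seed(
        derive_seed(config$seed, paste0("sample_", sid)), {
          # per-mass spatial residuals, column-major pixel order
          spat_mat <- if (config$spatial_sd > 0) {
            vapply(seq_len(nm), function(j) {
              f <- smooth_field(matrix(rnorm(h * w), h, w),
                                config$spatial_corr_length)
              as.vector(config$spatial_sd * (f - mean(f)) / sd(as.vector(f)))
            }, numeric(n_px_sample))
          } else {
            matrix(0, n_px_sample, nm)
          }
          jit <- if (config$mass_jitter_ppm > 0) {
            j <- rnorm(n_px_sample, 0, config$mass_jitter_ppm)
            pmax(pmin(j, 3 * config$mass_jitter_ppm),
                 -3 * config$mass_jitter_ppm)
          } else {
            numeric(n_px_sample)
          }
          meta_lab <- as.vector(tmap)
          rows <- render_sample_rows(config, axis, baseline, meta_lab,
                                     u[p, ], spat_mat, jit)
          list(rows = rows, lab = meta_lab,
               x = rep(0:(w - 1L), each = h), y = rep(0:(h - 1L), w))
        }
      )
      idx <- row + seq_len(n_px_sample)
      intensity[idx, ] <- sample_work$rows
      sample_ids[idx] <- sid
      patient_ids[idx] <- patients[p]
      xs[idx] <- sample_work$x
      ys[idx] <- sample_work$y
      labels[idx] <- sample_work$lab
      row <- row + n_px_sample
    }
  }
  names(tissue_maps) <- map_names

  dataset <- msi_dataset(
    mz = axis, intensity = intensity,
    pixels = tibble(
      sample_id = sample_ids, x = xs, y = ys,
      patient_id = patient_ids, tissue_label = labels
    ),
    polarity = config$polarity,
    provenance = list(generator_seed = config$seed)
  )
  truth <- structure(
    list(
      tissue_maps = tissue_maps,
      effect_table = sim_effect_table(config),
      patient_intercepts = tibble(
        patient_id = rep(patients, each = nm),
        mz = rep(panel$mz, config$n_patients),
        intercept = as.vector(t(u))
      ),
      seed = config$seed,
      config = config
    ),
    class = "msi_sim_truth"
  )
  list(dataset = dataset, truth = truth)
}

#' True log2 fold changes implied by a generator configuration
#' @param config an `msi_sim_config`.
#' @return tibble with columns `mz`, `pair`, `log2fc_true`.
#' @export
sim_effect_table <- function(config) {
  panel <- config$peak_panel
  dplyr::bind_rows(
    tibble(mz = panel$mz, pair = "cancer_vs_NCE",
           log2fc_true = panel$effect_cancer),
    tibble(mz = panel$mz, pair = "cancer_vs_stroma",
           log2fc_true = panel$effect_cancer - panel$effect_stroma),
    tibble(mz = panel$mz, pair = "stroma_vs_NCE",
           log2fc_true = panel$effect_stroma)
  )
}

#' Simulate an extracted peak matrix directly from the intensity model
#'
#' Fast path for Monte-Carlo studies of the statistical stages: draws
#' per-pixel peak heights from the same hierarchical model as
#' [generate_dataset()] (tissue effect + patient intercept + spatial residual
#' + log2 noise) and applies TIC-style normalization (each row divided by its
#' total signal including isotopes, matrix peaks and baseline area), skipping
#' spectral rendering and peak selection. Matrix-margin pixels are excluded,
#' matching the rows of a pipeline-extracted peak matrix.
#'
#' @param config an `msi_sim_config`.
#' @return a list with elements `peak_matrix` (an [msi_peakmatrix]) and
#'   `truth` (as in [generate_dataset()], without tissue maps rendered to
#'   spectra).
#' @export
simulate_peak_matrix <- function(config) {
  stopifnot(inherits(config, "msi_sim_config"))
  panel <- config$peak_panel
  nm <- nrow(panel)
  w <- config$grid[1]; h <- config$grid[2]
  patients <- sim_patient_ids(config)
  n_samples <- config$n_patients * config$samples_per_patient

  u <- with_seed(derive_seed(config$seed, "patient_intercepts"), {
    matrix(rnorm(config$n_patients * nm, 0, config$patient_sd),
           config$n_patients, nm, dimnames = list(patients, NULL))
  })
  iso_factor <- 1 + panel$iso2 + panel$iso3
  const_signal <- sum(config$matrix_peaks$intensity * (1 + config$matrix_peaks$iso2)) +
    sum(sim_baseline(config, sim_axis(config))) * config$axis_step /
    (config$peak_panel$sigma[1] * sqrt(2 * pi))

  vals <- list(); metas <- list(); maps <- vector("list", n_samples)
  map_names <- character(n_samples)
  s_idx <- 0L
  for (p in seq_len(config$n_patients)) {
    for (s in seq_len(config$samples_per_patient)) {
      s_idx <- s_idx + 1L
      sid <- sprintf("s%02d_%s", s, patients[p])
      map_names[s_idx] <- sid
      tmap <- generate_tissue_map(
        w, h, config$proportions, config$spatial_corr_length,
        derive_seed(config$seed, paste0("map_", sid))
      )
      maps[[s_idx]] <- tmap
      keep <- which(tmap != "matrix", arr.ind = TRUE)
      n_px <- nrow(keep)
      labs <- tmap[keep]
      res <- with_seed(derive_seed(config$seed, paste0("sample_", sid)), {
        spat <- if (config$spatial_sd > 0) {
          vapply(seq_len(nm), function(j) {
            f <- smooth_field(matrix(rnorm(h * w), h, w),
                              config$spatial_corr_length)
            f <- config$spatial_sd * (f - mean(f)) / sd(as.vector(f))
            f[keep]
          }, numeric(n_px))
        } else {
          matrix(0, n_px, nm)
        }
        eff <- matrix(0, n_px, nm)
        eff[labs == "stroma", ] <- matrix(panel$effect_stroma,
                                          sum(labs == "stroma"), nm,
                                          byrow = TRUE)
        eff[labs == "cancer", ] <- matrix(panel$effect_cancer,
                                          sum(labs == "cancer"), nm,
                                          byrow = TRUE)
        log2h <- matrix(panel$base_log2, n_px, nm, byrow = TRUE) + eff +
          matrix(u[p, ], n_px, nm, byrow = TRUE) + spat +
          matrix(rnorm(n_px * nm, 0, config$noise_sd), n_px, nm)
        raw <- 2^log2h
        tic <- as.vector(raw %*% iso_factor) + const_signal
        raw / tic
      })
      vals[[s_idx]] <- res
      metas[[s_idx]] <- tibble(
        sample_id = sid, patient_id = patients[p],
        x = keep[, "col"] - 1L, y = keep[, "row"] - 1L,
        tissue_label = labs
      )
    }
  }
  names(maps) <- map_names
  pm <- msi_peakmatrix(
    values = do.call(rbind, vals),
    row_meta = dplyr::bind_rows(metas),
    col_meta = tibble(mz = panel$mz)
  )
  truth <- structure(
    list(
      tissue_maps = maps,
      effect_table = sim_effect_table(config),
      patient_intercepts = tibble(
        patient_id = rep(patients, each = nm),
        mz = rep(panel$mz, config$n_patients),
        intercept = as.vector(t(u))
      ),
      seed = config$seed,
      config = config
    ),
    class = "msi_sim_truth"
  )
  list(peak_matrix = pm, truth = truth)
}

#' Write generator ground truth as plain-text tables and label images
#'
#' Emits `effects.tsv` (true per-pair log2 fold changes), `patients.tsv`
#' (per patient-and-mass intercepts), and per sample a label CSV plus a
#' grayscale PNG of the tissue map (matrix 0, NCE 1/3, stroma 2/3, cancer 1).
#'
#' @param truth an `msi_sim_truth`.
#' @param dir output directory (created if needed).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(truth$effect_table, file.path(dir, "effects.tsv"))
  readr::write_tsv(truth$patient_intercepts, file.path(dir, "patients.tsv"))
  shade <- c(matrix = 0, NCE = 1 / 3, stroma = 2 / 3, cancer = 1)
  for (nm in names(truth$tissue_maps)) {
    m <- truth$tissue_maps[[nm]]
    utils::write.csv(m, file.path(dir, paste0("tissue_map_", nm, ".csv")),
                     row.names = FALSE)
    img <- matrix(shade[m], nrow(m), ncol(m))
    png::writePNG(img, file.path(dir, paste0("tissue_map_", nm, ".png")))
  }
  invisible(dir)
}
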
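#' Pipeline configuration
#'
#' Collects the preprocessing and analysis settings of the full pipeline.
#' Polarity-dependent defaults follow MALDI-TOF prostate-MSI practice: an
#' absolute peak-selection threshold of 0.25 (positive mode) or 0.2
#' (negative mode) in base-peak-100 units, and peak-height extraction
#' intervals of 150 ppm (positive) or 200 ppm (negative) total width.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param calibrants optional data frame (`mz`, `tolerance_ppm`) enabling
#'   per-spectrum recalibration.
#' @param snr_min minimum signal-to-noise ratio for peak selection.
#' @param abs_threshold absolute intensity threshold on the base-peak-100
#'   scaled mean spectra; default 0.25/0.2 by polarity.
#' @param window_ppm total extraction interval width in ppm; default 150/200
#'   by polarity.
#' @param baseline_precision,baseline_relative_offset see
#'   [baseline_correct()].
#' @param iso_tol_ppm deisotoping tolerance.
#' @param n_orth orthogonal components in each OPLS-DA model.
#' @param n_perm permutations for the OPLS-DA significance test (desk-scale
#'   default 199; set 1000 for full-scale runs).
#' @param lmm an [iterative_config()] (desk-scale default `n_iter = 200`;
#'   set 1000 for full-scale runs).
#' @param exclusion_mz masses (e.g. known lipid fragments) removed from the
#'   merged peak list.
#' @param identity_lookup optional identity tibble or CSV path (see
#'   [read_identity_lookup()]).
#' @param seed root seed; permutation and LMM sub-streams derive from it.
#' @return an object of class `msi_pipeline_config`.
#' @export
pipeline_config <- function(polarity = "positive",
                            calibrants = NULL,
                            snr_min = 2,
                            abs_threshold = NULL,
                            window_ppm = NULL,
                            baseline_precision = 20,
                            baseline_relative_offset = 25,
                            iso_tol_ppm = 50,
                            n_orth = 1,
                            n_perm = 199,
                            lmm = iterative_config(n_iter = 200),
                            exclusion_mz = numeric(0),
                            identity_lookup = NULL,
                            seed = 1) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  if (is.null(abs_threshold)) {
    abs_threshold <- if (polarity == "positive") 0.25 else 0.2
  }
  if (is.null(window_ppm)) {
    window_ppm <- if (polarity == "positive") 150 else 200
  }
  if (abs_threshold <= 0 || window_ppm <= 0) {
    abort("Thresholds and windows must be positive.")
  }
  if (is.character(identity_lookup)) {
    identity_lookup <- read_identity_lookup(identity_lookup)
  }
  structure(
    list(
      polarity = polarity, calibrants = calibrants, snr_min = snr_min,
      abs_threshold = abs_threshold, window_ppm = window_ppm,
      baseline_precision = baseline_precision,
      baseline_relative_offset = baseline_relative_offset,
      iso_tol_ppm = iso_tol_ppm, n_orth = n_orth, n_perm = n_perm,
      lmm = lmm, exclusion_mz = exclusion_mz,
      identity_lookup = identity_lookup, seed = as.integer(seed)
    ),
    class = "msi_pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' The file may set any argument of [pipeline_config()] (scalars and the
#' nested `lmm` block with `fraction`, `n_iter`, `alpha`, `seed`); unknown
#' keys are rejected so typos surface immediately, and all values pass
#' through [pipeline_config()]'s validation.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `msi_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort("Config file must be .yaml, .yml or .json.")
  )
  allowed <- setdiff(names(formals(pipeline_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    abort(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$lmm)) {
    lmm_allowed <- names(formals(iterative_config))
    lmm_unknown <- setdiff(names(raw$lmm), lmm_allowed)
    if (length(lmm_unknown)) {
      abort(paste0("Unknown lmm config keys: ",
                   paste(lmm_unknown, collapse = ", ")))
    }
    raw$lmm <- do.call(iterative_config, raw$lmm)
  }
  if (!is.null(raw$calibrants)) {
    raw$calibrants <- as_tibble(as.data.frame(raw$calibrants))
  }
  do.call(pipeline_config, raw)
}

#' The three pairwise tissue comparisons
#' @noRd
TISSUE_PAIRS <- list(
  cancer_vs_NCE = c("cancer", "NCE"),
  cancer_vs_stroma = c("cancer", "stroma"),
  stroma_vs_NCE = c("stroma", "NCE")
)

#' Run the full preprocessing and analysis pipeline
#'
#' Executes, in order: (optional) calibrant recalibration, TIC
#' normalization, per-tissue mean spectra, baseline correction,
#' matrix-spectrum subtraction, peak selection with deisotoping and
#' duplicate removal, ppm-window peak-height extraction, auto-scaled PCA,
#' and per tissue pair OPLS-DA (with leave-one-patient-out CV, permutation
#' testing, VIP scores), iterative LMM testing, log2 fold changes, and the
#' assembled differential table. Deterministic given `config$seed`.
#'
#' @param dataset an annotated [msi_dataset] containing NCE, stroma, cancer
#'   and matrix pixels.
#' @param config an [pipeline_config()].
#' @return an object of class `msi_results` (the results bundle).
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "msi_dataset"),
            inherits(config, "msi_pipeline_config"))
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  config_hash <- rlang::hash(config)
  note("Run seed %d, config hash %s", config$seed,
       substr(config_hash, 1, 12))

  present <- unique(dataset$pixels$tissue_label)
  missing <- setdiff(c("NCE", "stroma", "cancer", "matrix"), present)
  if (length(missing)) {
    abort(paste0("Dataset is missing tissue label(s): ",
                 paste(missing, collapse = ", ")))
  }

  if (!is.null(config$calibrants)) {
    note("Recalibrating %d spectra against %d calibrants",
         n_spectra(dataset), nrow(config$calibrants))
    dataset <- recalibrate_dataset(dataset, config$calibrants)
  }
  note("TIC-normalizing %d spectra", n_spectra(dataset))
  dataset <- tic_normalize(dataset)
  invisible(gc(verbose = FALSE))

  note("Computing per-tissue mean spectra")
  means <- lapply(setNames(ANNOT_LABELS, ANNOT_LABELS), function(lb) {
    baseline_correct(mean_spectrum(dataset, lb),
                     precision = config$baseline_precision,
                     relative_offset = config$baseline_relative_offset)
  })
  tissue_lists <- lapply(c("NCE", "stroma", "cancer"), function(lb) {
    m <- subtract_matrix(means[[lb]], means[["matrix"]])
    # scale to base peak = 100 so the absolute threshold is in percent-of-
    # base-peak units
    m$intensity <- m$intensity * 100 / max(m$intensity)
    pl <- pick_peaks(m, snr_min = config$snr_min,
                     abs_threshold = config$abs_threshold)
    deisotope(pl, iso_tol_ppm = config$iso_tol_ppm)
  })
  merged <- merge_peaklists(tissue_lists, window_ppm = config$window_ppm)
  merged <- exclude_masses(merged, config$exclusion_mz)
  if (nrow(merged) == 0) abort("Peak selection produced an empty peak list.")
  note("Merged peak list: %d masses", nrow(merged))

  pm <- extract_peak_matrix(dataset, merged, window_ppm = config$window_ppm)
  note("Extracted peak matrix: %d spectra x %d masses",
       nrow(pm$values), ncol(pm$values))

  sc_all <- suppressWarnings(autoscale(pm))
  pca <- msi_pca(sc_all$x, n_components = min(2, ncol(sc_all$x)))
  pca_scores <- dplyr::bind_cols(pm$row_meta, as_tibble(pca$scores))

  comparisons <- list()
  for (pair_name in names(TISSUE_PAIRS)) {
    pair <- TISSUE_PAIRS[[pair_name]]
    note("Comparison %s", pair_name)
    keep <- pm$row_meta$tissue_label %in% pair
    sub <- subset_peakmatrix(pm, keep)
    sc <- suppressWarnings(autoscale(sub))
    labels <- sub$row_meta$tissue_label
    model <- fit_oplsda(sc$x, labels, n_orth = config$n_orth,
                        positive_class = pair[1])
    kept_mz <- sub$col_meta$mz[sc$params$kept]
    vip_tbl <- tibble(mz = kept_mz, vip = unname(vip_scores(model)))
    cv <- suppressWarnings(
      lopo_cv(sub$values, labels, sub$row_meta$patient_id,
              n_orth = config$n_orth, positive_class = pair[1])
    )
    perm <- permutation_test(
      sub$values, labels, sub$row_meta$patient_id,
      n_orth = config$n_orth, n_perm = config$n_perm,
      seed = derive_seed(config$seed, paste0("perm_", pair_name)),
      positive_class = pair[1]
    )
    lmm_cfg <- config$lmm
    lmm_cfg$seed <- derive_seed(config$seed, paste0("lmm_", pair_name))
    lmm_tbl <- iterative_lmm(sub, pair, config = lmm_cfg)
    lfc <- log2fc(sub, pair)
    # restrict to columns retained by auto-scaling so keys match the VIPs
    lfc_k <- lfc[lfc$mz %in% kept_mz, ]
    lmm_k <- lmm_tbl[lmm_tbl$mz %in% kept_mz, ]
    diff_tbl <- assemble_diff_table(
      lfc_k, lmm_k, vip_tbl, lookup = config$identity_lookup,
      alpha = config$lmm$alpha
    )
    comparisons[[pair_name]] <- list(
      pair = pair, model = model, vip = vip_tbl, cv = cv, perm = perm,
      lmm = lmm_tbl, log2fc = lfc, diff = diff_tbl
    )
    note("  CV accuracy %.3f, permutation p %.4g", cv$accuracy, perm$p_value)
  }

  structure(
    list(
      config = config,
      config_hash = config_hash,
      seed = config$seed,
      peak_list = merged,
      peak_matrix = pm,
      pca = pca,
      pca_scores = pca_scores,
      comparisons = comparisons,
      dataset_summary = dplyr::count(dataset$pixels, .data$tissue_label),
      log = log_lines
    ),
    class = "msi_results"
  )
}

#' @exportS3Method base::print
print.msi_results <- function(x, ...) {
  cat(sprintf("<msi_results> %d masses, %d comparisons; seed %d, config %s\n",
              nrow(x$peak_list), length(x$comparisons), x$seed,
              substr(x$config_hash, 1, 8)))
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    cat(sprintf("  %-18s accuracy %.3f  perm p %.4g  significant masses %d\n",
                nm, cmp$cv$accuracy, cmp$perm$p_value,
                sum(cmp$diff$significant)))
  }
  invisible(x)
}

#' Summary table across comparisons
#' @param x an `msi_results`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.msi_results <- function(x, ...) {
  purrr::map_dfr(names(x$comparisons), function(nm) {
    cmp <- x$comparisons[[nm]]
    tibble(
      comparison = nm, accuracy = cmp$cv$accuracy,
      perm_p = cmp$perm$p_value,
      n_significant = sum(cmp$diff$significant),
      n_masses = nrow(cmp$diff)
    )
  })
}

#' Combined differential table across comparisons
#' @param x an `msi_results`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.msi_results <- function(x, ...) {
  purrr::map_dfr(names(x$comparisons), function(nm) {
    dplyr::mutate(as_tibble(x$comparisons[[nm]]$diff), comparison = nm,
                  .before = 1)
  })
}

# Recalibrate every spectrum and re-interpolate onto the shared axis.
#' @noRd
recalibrate_dataset <- function(dataset, calibrants) {
  axis <- dataset$mz
  for (i in seq_len(n_spectra(dataset))) {
    sp <- get_spectrum(dataset, i)
    rc <- withCallingHandlers(
      recalibrate(sp, calibrants),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (identical(rc$flags$recalibration, "ok")) {
      dataset$intensity[i, ] <- approx(rc$mz, rc$intensity, xout = axis,
                                       rule = 1)$y
    }
  }
  dataset$intensity[is.na(dataset$intensity)] <- 0
  dataset
}

#' Render per-sample ion images for one mass
#'
#' Extracts the highest data point within the ppm window around `mz` for
#' every pixel and scales linearly to each sample's 99th percentile.
#' Unannotated pixels get `NA` intensity (rendered transparent).
#'
#' @param dataset an [msi_dataset].
#' @param mz target mass (must lie within the dataset's axis range).
#' @param window_ppm total window width in ppm.
#' @return a tibble of class `msi_ion_image` with `sample_id`, `x`, `y`,
#'   `intensity`, `scaled`.
#' @export
render_ion_image <- function(dataset, mz, window_ppm = 150) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (n_spectra(dataset) == 0) abort("Dataset has no pixels.")
  if (mz < min(dataset$mz) || mz > max(dataset$mz)) {
    abort(sprintf("m/z %.4f outside the dataset range [%.2f, %.2f].",
                  mz, min(dataset$mz), max(dataset$mz)))
  }
  half <- ppm_halfwidth(mz, window_ppm)
  lo <- findInterval(mz - half, dataset$mz) + 1L
  hi <- max(findInterval(mz + half, dataset$mz), lo)
  sub <- dataset$intensity[, lo:hi, drop = FALSE]
  val <- if (ncol(sub) == 1) sub[, 1] else do.call(pmax, asplit(sub, 2))
  img <- dplyr::mutate(
    dataset$pixels,
    intensity = ifelse(.data$tissue_label == "unannotated", NA_real_, val)
  )
  img <- img |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      q99 = quantile(.data$intensity, 0.99, na.rm = TRUE),
      scaled = pmin(.data$intensity / ifelse(.data$q99 > 0, .data$q99, 1), 1)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"q99")
  attr(img, "mz") <- mz
  class(img) <- c("msi_ion_image", class(img))
  img
}

#' @exportS3Method ggplot2::autoplot
autoplot.msi_ion_image <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       fill = .data$scaled)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "transparent",
                                  name = "rel. intensity") +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("m/z %.4f", attr(object, "mz"))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.msi_oplsda <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$loading, .data$vip)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(
      x = sprintf("loading on predictive LV (%s → positive)",
                  object$positive_class),
      y = "VIP"
    ) +
    ggplot2::theme_minimal()
}

#' @param object an `msi_diff_result`.
#' @param ... unused.
#' @rdname assemble_diff_table
#' @exportS3Method ggplot2::autoplot
autoplot.msi_diff_result <- function(object, ...) {
  d <- dplyr::mutate(as_tibble(object),
                     neglogp = -log10(pmax(.data$mean_adj_p, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, .data$neglogp,
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 mean adjusted p") +
    ggplot2::theme_minimal()
}

#' Write a results bundle to disk
#'
#' Emits the merged peak list, peak matrix, PCA scores/loadings, and per
#' comparison the model summary, VIPs, CV predictions, permutation summary
#' and differential table, all as TSV; ion images of the top-VIP mass per
#' comparison as PNG (when a dataset is supplied); and a machine-readable
#' `manifest.json` recording the configuration, seed, config hash, package
#' version and every emitted file. Refuses to overwrite an existing results
#' directory unless `force = TRUE`.
#'
#' @param bundle an `msi_results`.
#' @param out_dir output directory.
#' @param dataset optional [msi_dataset] used to render ion images.
#' @param force overwrite an existing manifest.
#' @return `out_dir`, invisibly.
#' @export
write_results_tables <- function(bundle, out_dir, dataset = NULL,
                                 force = FALSE) {
  stopifnot(inherits(bundle, "msi_results"))
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    abort(paste0("Results already exist in ", out_dir,
                 "; use force = TRUE to overwrite."))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(as_tibble(tbl), path)
    files <<- c(files, name)
  }
  emit(bundle$peak_list, "peak_list.tsv")
  write_peakmatrix(bundle$peak_matrix, file.path(out_dir, "peak_matrix.tsv"))
  files <- c(files, "peak_matrix.tsv", "peak_matrix.tsv.cols.tsv")
  emit(bundle$pca_scores, "pca_scores.tsv")
  emit(dplyr::bind_cols(
    tibble(variable = rownames(bundle$pca$loadings)),
    as_tibble(bundle$pca$loadings)
  ), "pca_loadings.tsv")
  for (nm in names(bundle$comparisons)) {
    cmp <- bundle$comparisons[[nm]]
    emit(tidy(cmp$model), sprintf("oplsda_%s.tsv", nm))
    emit(tidy(cmp$cv), sprintf("cv_predictions_%s.tsv", nm))
    emit(glance(cmp$perm), sprintf("permutation_%s.tsv", nm))
    emit(cmp$diff, sprintf("diff_%s.tsv", nm))
    if (!is.null(dataset)) {
      top <- cmp$vip$mz[which.max(cmp$vip$vip)]
      img <- render_ion_image(dataset, top, bundle$config$window_ppm)
      png_name <- sprintf("ion_image_%s.png", nm)
      write_ion_image_png(img, file.path(out_dir, png_name))
      files <- c(files, png_name)
    }
  }
  emit(glance(bundle), "summary.tsv")
  manifest <- list(
    seed = bundle$seed,
    config_hash = bundle$config_hash,
    package_version = as.character(utils::packageVersion("msidiff")),
    r_version = R.version.string,
    config = serialize_config(bundle$config),
    files = c(files, "manifest.json")
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @noRd
serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$lmm <- unclass(cfg$lmm)
  cfg
}

# Grayscale PNG per sample, tiled horizontally with 2-px gaps.
#' @noRd
write_ion_image_png <- function(img, path) {
  samples <- unique(img$sample_id)
  mats <- lapply(samples, function(s) {
    sub <- img[img$sample_id == s, ]
    m <- matrix(0, max(sub$y) + 1, max(sub$x) + 1)
    m[cbind(sub$y + 1, sub$x + 1)] <- ifelse(is.na(sub$scaled), 0, sub$scaled)
    m
  })
  h <- max(vapply(mats, nrow, integer(1)))
  mats <- lapply(mats, function(m) rbind(m, matrix(0, h - nrow(m), ncol(m))))
  gap <- matrix(0, h, 2)
  tiled <- do.call(cbind, Reduce(function(a, b) c(a, list(gap, b)),
                                 mats[-1], list(mats[[1]])))
  png::writePNG(tiled, path)
  invisible(path)
}
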
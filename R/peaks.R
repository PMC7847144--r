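#' Construct a peak list
#'
#' A tibble of peaks sorted by m/z with attributes for the ion mode and, once
#' set at extraction time, the ppm interval width. Used both for per-tissue
#' peak lists and the merged panel.
#'
#' @param peaks tibble with columns `mz`, `height`, `snr`, `source_tissue`.
#' @param polarity ion mode.
#' @param extraction_ppm optional total ppm window width for extraction.
#' @return an object of class `msi_peaklist` (a tibble).
#' @export
msi_peaklist <- function(peaks, polarity = "positive", extraction_ppm = NA) {
  peaks <- as_tibble(peaks)
  req <- c("mz", "height", "snr", "source_tissue")
  if (!all(req %in% names(peaks))) {
    abort(paste0("Peak list needs columns: ", paste(req, collapse = ", ")))
  }
  if (is.unsorted(peaks$mz, strictly = FALSE)) {
    peaks <- peaks[order(peaks$mz), ]
  }
  structure(
    peaks,
    polarity = polarity, extraction_ppm = extraction_ppm,
    class = c("msi_peaklist", class(tibble())))
}

#' Pick peaks from a (baseline-corrected) spectrum
#'
#' Local maxima strictly greater than both neighbours, kept when the height
#' reaches `abs_threshold` and the signal-to-noise ratio reaches `snr_min`.
#' Noise is a robust `1.4826 * MAD` estimate over a sliding window of
#' `noise_window` data points (evaluated on a stride and interpolated).
#' Apex m/z is refined by 3-point parabolic interpolation.
#'
#' @param spectrum an [msi_spectrum], baseline-corrected.
#' @param snr_min minimum signal-to-noise ratio.
#' @param abs_threshold absolute intensity threshold (same units as the
#'   spectrum).
#' @param noise_window sliding-window length in data points.
#' @return an `msi_peaklist` (possibly empty).
#' @export
pick_peaks <- function(spectrum, snr_min = 2, abs_threshold, noise_window = 501) {
  stopifnot(inherits(spectrum, "msi_spectrum"))
  y <- spectrum$intensity
  n <- length(y)
  if (n < 3) {
    return(msi_peaklist(tibble(mz = numeric(0), height = numeric(0),
                               snr = numeric(0), source_tissue = character(0)),
                        polarity = spectrum$polarity))
  }
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  cand <- cand[y[cand] >= abs_threshold]
  if (length(cand) == 0) {
    return(msi_peaklist(tibble(mz = numeric(0), height = numeric(0),
                               snr = numeric(0), source_tissue = character(0)),
                        polarity = spectrum$polarity))
  }
  noise <- rolling_noise(y, noise_window)
  snr <- ifelse(noise[cand] > 0, y[cand] / noise[cand], Inf)
  keep <- snr >= snr_min
  cand <- cand[keep]
  snr <- snr[keep]
  mz_refined <- vapply(cand, function(i) refine_apex(spectrum$mz,
                                                     y, i), numeric(1))
  msi_peaklist(
    tibble(mz = mz_refined, height = y[cand], snr = snr,
           source_tissue = spectrum$tissue_label),
    polarity = spectrum$polarity
  )
}

# Robust rolling noise (1.4826*MAD) evaluated every `stride` points and
# linearly interpolated; window length `width` data points.
#' @noRd
rolling_noise <- function(y, width = 501, stride = 50) {
  n <- length(y)
  half <- width %/% 2
  anchors <- unique(c(seq(1, n, by = stride), n))
  vals <- vapply(anchors, function(i) {
    mad(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  if (length(anchors) == 1) return(rep(vals, n))
  approx(anchors, vals, xout = seq_len(n), rule = 2)$y
}

#' Remove isotope peaks from a peak list
#'
#' A peak is removed when it sits within `iso_tol_ppm` of
#' `parent + k * 1.00335` Da (k = 1..3) of a more intense peak at lower m/z.
#'
#' @param peaks an `msi_peaklist`, sorted by m/z.
#' @param iso_tol_ppm matching tolerance in ppm.
#' @return the deisotoped `msi_peaklist`.
#' @export
deisotope <- function(peaks, iso_tol_ppm = 50) {
  stopifnot(inherits(peaks, "msi_peaklist"))
  n <- nrow(peaks)
  if (n <= 1) return(peaks)
  remove <- logical(n)
  for (i in seq_len(n - 1)) {
    for (k in 1:3) {
      target <- peaks$mz[i] + k * ISOTOPE_DA
      hits <- which(
        ppm_diff(peaks$mz, target) <= iso_tol_ppm &
          peaks$height < peaks$height[i]
      )
      remove[hits] <- TRUE
    }
  }
  msi_peaklist(peaks[!remove, ],
               polarity = attr(peaks, "polarity"),
               extraction_ppm = attr(peaks, "extraction_ppm"))
}

#' Merge per-tissue peak lists and remove duplicates
#'
#' Pools the lists, sorts by m/z, clusters by single linkage at `window_ppm`
#' (consecutive peaks closer than the window join one cluster) and represents
#' each cluster by its intensity-weighted mean m/z. The result satisfies the
#' peak-list minimum-spacing invariant: no two peaks closer than
#' `window_ppm * mz / 1e6`.
#'
#' @param lists a list of `msi_peaklist` objects of the same polarity.
#' @param window_ppm clustering window in ppm.
#' @return the merged `msi_peaklist`.
#' @export
merge_peaklists <- function(lists, window_ppm) {
  stopifnot(length(lists) >= 1)
  pols <- unique(vapply(lists, function(l) attr(l, "polarity"), character(1)))
  if (length(pols) > 1) abort("Peak lists differ in polarity.")
  pooled <- dplyr::bind_rows(lapply(lists, as_tibble))
  if (nrow(pooled) == 0) {
    return(msi_peaklist(pooled, polarity = pols))
  }
  pooled <- pooled[order(pooled$mz), ]
  gap_ok <- diff(pooled$mz) > window_ppm * pooled$mz[-1] / 1e6
  cluster <- cumsum(c(TRUE, gap_ok))
  merged <- pooled |>
    dplyr::mutate(cluster = cluster) |>
    dplyr::group_by(cluster) |>
    dplyr::summarise(
      mz = sum(.data$mz * .data$height) / sum(.data$height),
      height = max(.data$height),
      snr = max(.data$snr),
      source_tissue = paste(sort(unique(.data$source_tissue)),
                            collapse = "+"),
      .groups = "drop"
    ) |>
    dplyr::select(-"cluster")
  msi_peaklist(merged, polarity = pols)
}

#' Drop peaks on an exclusion-mass list
#'
#' Removes peaks within `tol_ppm` of any excluded mass (e.g. lipid fragments
#' identified by tandem MS).
#'
#' @param peaks an `msi_peaklist`.
#' @param exclusion_mz numeric vector of masses to exclude.
#' @param tol_ppm matching tolerance in ppm.
#' @return the filtered `msi_peaklist`.
#' @export
exclude_masses <- function(peaks, exclusion_mz, tol_ppm = 50) {
  stopifnot(inherits(peaks, "msi_peaklist"))
  if (length(exclusion_mz) == 0 || nrow(peaks) == 0) return(peaks)
  drop <- vapply(peaks$mz, function(m) {
    any(ppm_diff(m, exclusion_mz) <= tol_ppm)
  }, logical(1))
  msi_peaklist(peaks[!drop, ], polarity = attr(peaks, "polarity"),
               extraction_ppm = attr(peaks, "extraction_ppm"))
}

#' Construct a peak matrix
#'
#' Extracted peak heights (spectra x masses) with row metadata describing
#' each contributing pixel and column metadata describing each mass.
#'
#' @param values numeric matrix, one row per spectrum, one column per mass.
#' @param row_meta tibble with `sample_id`, `patient_id`, `x`, `y`,
#'   `tissue_label`.
#' @param col_meta tibble with at least `mz`.
#' @return an object of class `msi_peakmatrix`.
#' @export
msi_peakmatrix <- function(values, row_meta, col_meta) {
  values <- as.matrix(values)
  row_meta <- as_tibble(row_meta)
  col_meta <- as_tibble(col_meta)
  if (nrow(values) != nrow(row_meta)) {
    abort("`row_meta` must align 1:1 with the rows of `values`.")
  }
  if (ncol(values) != nrow(col_meta)) {
    abort("`col_meta` must align 1:1 with the columns of `values`.")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("Peak-matrix values must be finite and non-negative.")
  }
  colnames(values) <- sprintf("mz_%.4f", col_meta$mz)
  structure(list(values = values, row_meta = row_meta, col_meta = col_meta),
            class = "msi_peakmatrix")
}

#' @exportS3Method base::print
print.msi_peakmatrix <- function(x, ...) {
  cat(sprintf("<msi_peakmatrix> %d spectra x %d masses (m/z %.2f-%.2f)\n",
              nrow(x$values), ncol(x$values),
              min(x$col_meta$mz), max(x$col_meta$mz)))
  print(table(x$row_meta$tissue_label))
  invisible(x)
}

#' @exportS3Method base::dim
dim.msi_peakmatrix <- function(x) dim(x$values)

#' Long tidy view of a peak matrix
#' @param x an `msi_peakmatrix`.
#' @param ... unused.
#' @return a tibble with one row per (spectrum, mass) pair.
#' @exportS3Method generics::tidy
tidy.msi_peakmatrix <- function(x, ...) {
  wide <- dplyr::bind_cols(x$row_meta, as_tibble(x$values))
  tidyr::pivot_longer(wide, dplyr::starts_with("mz_"),
                      names_to = "mass", values_to = "height") |>
    dplyr::mutate(mz = x$col_meta$mz[match(.data$mass,
                                           colnames(x$values))]) |>
    dplyr::select(-"mass")
}

#' Keep a subset of peak-matrix rows
#' @param pm an `msi_peakmatrix`.
#' @param idx logical or integer row index.
#' @export
subset_peakmatrix <- function(pm, idx) {
  msi_peakmatrix(pm$values[idx, , drop = FALSE], pm$row_meta[idx, ],
                 pm$col_meta)
}

#' Extract the spectra-by-masses peak matrix
#'
#' For every annotated non-matrix spectrum and every peak, takes the highest
#' data point inside the total ppm interval centred on the peak m/z
#' (`[mz (1 - w/2e6), mz (1 + w/2e6)]`), tolerating the minor mass shifts
#' from spectrum to spectrum. Windows of neighbouring peaks must not overlap.
#'
#' @param dataset a TIC-normalized [msi_dataset].
#' @param peaks an `msi_peaklist` (typically the merged panel).
#' @param window_ppm total interval width in ppm.
#' @return an `msi_peakmatrix`.
#' @export
extract_peak_matrix <- function(dataset, peaks, window_ppm) {
  stopifnot(inherits(dataset, "msi_dataset"), inherits(peaks, "msi_peaklist"))
  if (nrow(peaks) == 0) abort("Empty peak list.")
  mzs <- peaks$mz
  lower <- mzs * (1 - window_ppm / 2e6)
  upper <- mzs * (1 + window_ppm / 2e6)
  if (any(upper[-length(upper)] >= lower[-1])) {
    abort("Overlapping extraction windows: peak spacing violates the peak-list invariant.")
  }
  rows <- which(dataset$pixels$tissue_label %in% c("NCE", "stroma", "cancer"))
  if (length(rows) == 0) abort("No annotated non-matrix spectra to extract.")
  vals <- matrix(0, length(rows), length(mzs))
  for (j in seq_along(mzs)) {
    lo <- findInterval(lower[j], dataset$mz) + 1L
    hi <- findInterval(upper[j], dataset$mz)
    if (hi < lo) next
    sub <- dataset$intensity[rows, lo:hi, drop = FALSE]
    vals[, j] <- if (ncol(sub) == 1) sub[, 1] else do.call(pmax, asplit(sub, 2))
  }
  msi_peakmatrix(
    values = vals,
    row_meta = dataset$pixels[rows, ],
    col_meta = tibble(mz = mzs)
  )
}

#' Write a peak list as TSV
#' @param peaks an `msi_peaklist`.
#' @param path output path.
#' @export
write_peaklist <- function(peaks, path) {
  readr::write_tsv(as_tibble(peaks), path)
  invisible(path)
}

#' Write a peak matrix as TSV (values plus row metadata) with a column
#' metadata sidecar `<path>.cols.tsv`
#' @param pm an `msi_peakmatrix`.
#' @param path output path.
#' @export
write_peakmatrix <- function(pm, path) {
  readr::write_tsv(dplyr::bind_cols(pm$row_meta, as_tibble(pm$values)), path)
  readr::write_tsv(pm$col_meta, paste0(path, ".cols.tsv"))
  invisible(path)
}
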
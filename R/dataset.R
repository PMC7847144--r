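#' Construct an in-memory MSI dataset
#'
#' Holds a collection of pixel spectra on one shared m/z axis (continuous
#' mode). Intensities are stored as an `n_pixels x n_points` matrix for
#' compactness; row order matches the `pixels` metadata table. Processed-mode
#' files are resampled onto a shared axis at read time, so the in-memory
#' representation is always continuous.
#'
#' @param mz shared m/z axis (Da), strictly increasing.
#' @param intensity numeric matrix, one row per pixel, `length(mz)` columns.
#' @param pixels tibble with columns `sample_id`, `patient_id`, `x`, `y`,
#'   `tissue_label`; the key `(sample_id, x, y)` must be unique.
#' @param polarity `"positive"` or `"negative"`.
#' @param provenance optional named list recording origins (paths, seeds).
#' @return an object of class `msi_dataset`.
#' @export
msi_dataset <- function(mz, intensity, pixels, polarity = "positive",
                        provenance = list()) {
  mz <- as.numeric(mz)
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    abort("Shared m/z axis must be strictly increasing.")
  }
  if (!is.matrix(intensity)) intensity <- matrix(intensity, nrow = 1)
  if (ncol(intensity) != length(mz)) {
    abort("`intensity` must have one column per m/z axis point.")
  }
  pixels <- as_tibble(pixels)
  req <- c("sample_id", "x", "y", "patient_id", "tissue_label")
  if (!all(req %in% names(pixels))) {
    abort(paste0("`pixels` must have columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(pixels) != nrow(intensity)) {
    abort("`pixels` rows must match `intensity` rows 1:1.")
  }
  bad <- setdiff(unique(pixels$tissue_label), TISSUE_LABELS)
  if (length(bad)) {
    abort(paste0("Unknown tissue labels: ", paste(bad, collapse = ", ")))
  }
  key <- paste(pixels$sample_id, pixels$x, pixels$y, sep = "\r")
  if (anyDuplicated(key)) {
    abort("Pixel keys (sample_id, x, y) must be unique.")
  }
  polarity <- match.arg(polarity, c("positive", "negative"))
  structure(
    list(
      mz = mz, intensity = intensity, pixels = pixels,
      shared_axis = TRUE, polarity = polarity, provenance = provenance
    ),
    class = "msi_dataset"
  )
}

#' @exportS3Method base::print
print.msi_dataset <- function(x, ...) {
  counts <- table(factor(x$pixels$tissue_label, levels = TISSUE_LABELS))
  cat(sprintf(
    "<msi_dataset> %d spectra, %d axis points (m/z %.2f-%.2f), %s mode\n",
    n_spectra(x), length(x$mz), min(x$mz), max(x$mz), x$polarity
  ))
  cat("  samples:", length(unique(x$pixels$sample_id)),
      " patients:", length(unique(x$pixels$patient_id)), "\n")
  cat("  labels: ", paste(names(counts), counts, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Number of spectra in a dataset
#' @param dataset an [msi_dataset].
#' @export
n_spectra <- function(dataset) nrow(dataset$intensity)

#' Extract one pixel spectrum from a dataset
#' @param dataset an [msi_dataset].
#' @param i row index into the pixel table.
#' @return an [msi_spectrum].
#' @export
get_spectrum <- function(dataset, i) {
  stopifnot(inherits(dataset, "msi_dataset"), i >= 1, i <= n_spectra(dataset))
  px <- dataset$pixels[i, ]
  msi_spectrum(
    mz = dataset$mz, intensity = dataset$intensity[i, ],
    x = px$x, y = px$y, sample_id = px$sample_id,
    patient_id = px$patient_id, tissue_label = px$tissue_label,
    polarity = dataset$polarity
  )
}

#' Keep a subset of pixels
#' @param dataset an [msi_dataset].
#' @param idx logical or integer row index.
#' @return an [msi_dataset] restricted to `idx`.
#' @export
subset_pixels <- function(dataset, idx) {
  msi_dataset(
    mz = dataset$mz,
    intensity = dataset$intensity[idx, , drop = FALSE],
    pixels = dataset$pixels[idx, ],
    polarity = dataset$polarity,
    provenance = dataset$provenance
  )
}

#' Pixel metadata as a tibble
#' @param x an [msi_dataset].
#' @param ... unused.
#' @exportS3Method tibble::as_tibble
as_tibble.msi_dataset <- function(x, ...) x$pixels
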
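#' Construct a single pixel spectrum
#'
#' A spectrum is one pixel's intensity profile over a strictly increasing m/z
#' axis, together with its pixel coordinates and sample/patient/histology
#' metadata. Pixel coordinates are 0-based, x increasing rightwards and y
#' downwards.
#'
#' @param mz numeric vector of m/z values (Da), strictly increasing.
#' @param intensity numeric vector of non-negative intensities, same length
#'   as `mz`.
#' @param x,y integer pixel coordinates (0-based).
#' @param sample_id,patient_id character identifiers.
#' @param tissue_label one of `"NCE"`, `"stroma"`, `"cancer"`, `"matrix"`,
#'   `"unannotated"`.
#' @param polarity `"positive"` or `"negative"`.
#' @param flags optional named list of processing flags (e.g. a recalibration
#'   warning).
#' @return an object of class `msi_spectrum`.
#' @export
msi_spectrum <- function(mz, intensity, x = 0L, y = 0L,
                         sample_id = "s1", patient_id = "p1",
                         tissue_label = "unannotated",
                         polarity = "positive", flags = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    abort("`mz` and `intensity` must have the same length.")
  }
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    abort("`mz` axis must be strictly increasing.")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    abort("Intensities must be finite and non-negative.")
  }
  tissue_label <- match.arg(tissue_label, TISSUE_LABELS)
  polarity <- match.arg(polarity, c("positive", "negative"))
  structure(
    list(
      mz = mz, intensity = intensity,
      x = as.integer(x), y = as.integer(y),
      sample_id = as.character(sample_id),
      patient_id = as.character(patient_id),
      tissue_label = tissue_label, polarity = polarity,
      flags = flags
    ),
    class = "msi_spectrum"
  )
}

#' @exportS3Method base::print
print.msi_spectrum <- function(x, ...) {
  cat(sprintf(
    "<msi_spectrum> %s pixel (%d,%d) [%s/%s] %s mode\n  %d points, m/z %.3f-%.3f, TIC %.4g\n",
    x$tissue_label, x$x, x$y, x$sample_id, x$patient_id, x$polarity,
    length(x$mz), min(x$mz), max(x$mz), sum(x$intensity)
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.msi_spectrum <- function(x, ...) {
  tibble(mz = x$mz, intensity = x$intensity)
}

#' Total ion count of a spectrum
#' @param spectrum an [msi_spectrum].
#' @return the sum of intensities.
#' @export
tic <- function(spectrum) {
  stopifnot(inherits(spectrum, "msi_spectrum"))
  sum(spectrum$intensity)
}
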
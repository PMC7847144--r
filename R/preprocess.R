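#' Recalibrate a spectrum against known calibrant masses
#'
#' Peak-realignment against a small set of calibrant masses: each calibrant is
#' searched for as a local maximum within its ppm tolerance, the apex m/z is
#' refined by 3-point parabolic interpolation, and a polynomial of mass error
#' versus m/z (cubic when four or more calibrants match, otherwise degree
#' `matches - 1`) is fitted to the matched apexes and subtracted from the
#' axis. With fewer than two matched calibrants the spectrum is returned
#' unchanged with a warning flag.
#'
#' @param spectrum an [msi_spectrum].
#' @param calibrants data frame with columns `mz` and `tolerance_ppm`.
#' @return the recalibrated [msi_spectrum]; `flags$recalibration` records
#'   `"ok"` or `"too_few_calibrants"`, and `flags$calibrants_matched` the
#'   match count.
#' @export
recalibrate <- function(spectrum, calibrants) {
  stopifnot(inherits(spectrum, "msi_spectrum"))
  calibrants <- as_tibble(calibrants)
  stopifnot(all(c("mz", "tolerance_ppm") %in% names(calibrants)))

  matched_mz <- numeric(0)
  matched_err <- numeric(0)
  for (i in seq_len(nrow(calibrants))) {
    apex <- find_apex_near(spectrum$mz, spectrum$intensity,
                           calibrants$mz[i], calibrants$tolerance_ppm[i])
    if (!is.na(apex)) {
      matched_mz <- c(matched_mz, calibrants$mz[i])
      matched_err <- c(matched_err, apex - calibrants$mz[i])
    }
  }
  n_matched <- length(matched_mz)
  if (n_matched < 2) {
    warn("Fewer than 2 calibrants matched; spectrum returned unchanged.")
    spectrum$flags$recalibration <- "too_few_calibrants"
    spectrum$flags$calibrants_matched <- n_matched
    return(spectrum)
  }
  degree <- min(3L, n_matched - 1L)
  fit <- lm(err ~ poly(mz, degree, raw = TRUE),
            data = data.frame(mz = matched_mz, err = matched_err))
  correction <- stats::predict(fit, newdata = data.frame(mz = spectrum$mz))
  new_axis <- spectrum$mz - correction
  if (any(diff(new_axis) <= 0)) {
    warn("Recalibration would break axis monotonicity; spectrum unchanged.")
    spectrum$flags$recalibration <- "non_monotone_correction"
    spectrum$flags$calibrants_matched <- n_matched
    return(spectrum)
  }
  spectrum$mz <- new_axis
  spectrum$flags$recalibration <- "ok"
  spectrum$flags$calibrants_matched <- n_matched
  spectrum
}

# Locate a local-maximum apex near `target` within `tol_ppm`; returns the
# parabolically refined apex m/z or NA.
#' @noRd
find_apex_near <- function(mz, intensity, target, tol_ppm) {
  half <- ppm_halfwidth(target, 2 * tol_ppm)
  lo <- findInterval(target - half, mz) + 1L
  hi <- findInterval(target + half, mz)
  if (hi - lo < 2) return(NA_real_)
  idx <- lo:hi
  y <- intensity[idx]
  best <- which.max(y)
  i <- idx[best]
  if (i <= 1 || i >= length(mz)) return(NA_real_)
  if (!(intensity[i] > intensity[i - 1] && intensity[i] > intensity[i + 1])) {
    return(NA_real_)
  }
  refine_apex(mz, intensity, i)
}

#' @noRd
refine_apex <- function(mz, intensity, i) {
  y0 <- intensity[i - 1]; y1 <- intensity[i]; y2 <- intensity[i + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y0 - y2) / denom
  delta <- max(min(delta, 0.5), -0.5)
  step <- (mz[i + 1] - mz[i - 1]) / 2
  mz[i] + delta * step
}

#' Normalize intensities to the total ion count
#'
#' Divides each spectrum's intensities by their sum, so the output sums to 1.
#' Idempotent. Errors on an all-zero spectrum.
#'
#' @param x an [msi_spectrum] or [msi_dataset].
#' @return the normalized object.
#' @export
tic_normalize <- function(x) UseMethod("tic_normalize")

#' @export
tic_normalize.msi_spectrum <- function(x) {
  s <- sum(x$intensity)
  if (s <= 0) abort("Cannot TIC-normalize an all-zero spectrum.")
  x$intensity <- x$intensity / s
  x
}

#' @export
tic_normalize.msi_dataset <- function(x) {
  s <- rowSums(x$intensity)
  if (any(s <= 0)) {
    abort(sprintf("Cannot TIC-normalize: %d all-zero spectra.", sum(s <= 0)))
  }
  x$intensity <- x$intensity / s
  x$provenance$tic_normalized <- TRUE
  x
}

#' Cross-patient mean spectrum for one tissue label
#'
#' Pointwise arithmetic mean of the TIC-normalized spectra carrying the
#' label (spectra are normalized internally, so the result is the same
#' whether or not the dataset was normalized beforehand).
#'
#' @param dataset an [msi_dataset] with a shared axis.
#' @param label tissue label to average over.
#' @return an [msi_spectrum] with `sample_id = "mean"`.
#' @export
mean_spectrum <- function(dataset, label) {
  stopifnot(inherits(dataset, "msi_dataset"))
  label <- match.arg(label, TISSUE_LABELS)
  idx <- which(dataset$pixels$tissue_label == label)
  if (length(idx) == 0) {
    abort(paste0("No spectra with label '", label, "'."))
  }
  s <- rowSums(dataset$intensity[idx, , drop = FALSE])
  if (any(s <= 0)) abort("All-zero spectrum encountered in mean_spectrum.")
  w <- numeric(n_spectra(dataset))
  w[idx] <- 1 / (s * length(idx))
  m <- as.vector(w %*% dataset$intensity)
  msi_spectrum(dataset$mz, m, sample_id = "mean", patient_id = "all",
               tissue_label = label, polarity = dataset$polarity)
}

#' Baseline-correct a spectrum
#'
#' The axis is split into `precision` equal-width segments; each segment
#' contributes an anchor at its midpoint with value
#' `segment minimum + (relative_offset/100) * local noise`, where noise is
#' the robust `1.4826 * MAD` of the segment's intensities. The baseline is
#' the linear interpolation through the anchors (flat extrapolation at the
#' ends) and is subtracted with clipping at zero. Parameter names and
#' defaults follow the (precision, relative offset) controls familiar from
#' desktop MS software.
#'
#' @param spectrum an [msi_spectrum].
#' @param precision number of segments (>= 2).
#' @param relative_offset percentage of local noise added to each anchor.
#' @return the corrected [msi_spectrum].
#' @export
baseline_correct <- function(spectrum, precision = 20, relative_offset = 25) {
  stopifnot(inherits(spectrum, "msi_spectrum"))
  if (precision < 2) abort("`precision` must be >= 2.")
  mz <- spectrum$mz
  y <- spectrum$intensity
  edges <- seq(min(mz), max(mz), length.out = precision + 1)
  seg <- pmin(findInterval(mz, edges, rightmost.closed = TRUE), precision)
  anchor_mz <- anchor_val <- numeric(0)
  for (k in seq_len(precision)) {
    in_seg <- seg == k
    if (!any(in_seg)) next
    ys <- y[in_seg]
    noise <- mad(ys)
    anchor_mz <- c(anchor_mz, (edges[k] + edges[k + 1]) / 2)
    anchor_val <- c(anchor_val, min(ys) + (relative_offset / 100) * noise)
  }
  baseline <- approx(anchor_mz, anchor_val, xout = mz, rule = 2)$y
  spectrum$intensity <- pmax(y - baseline, 0)
  spectrum
}

#' Subtract the matrix mean spectrum from a tissue mean spectrum
#'
#' Pointwise difference clipped at zero, removing chemical-background peaks
#' present in the matrix-only regions. Axes must be identical.
#'
#' @param tissue_mean,matrix_mean [msi_spectrum] objects on the same axis.
#' @return the background-subtracted [msi_spectrum].
#' @export
subtract_matrix <- function(tissue_mean, matrix_mean) {
  stopifnot(inherits(tissue_mean, "msi_spectrum"),
            inherits(matrix_mean, "msi_spectrum"))
  if (length(tissue_mean$mz) != length(matrix_mean$mz) ||
      any(tissue_mean$mz != matrix_mean$mz)) {
    abort("Axis mismatch between tissue and matrix mean spectra.")
  }
  tissue_mean$intensity <- pmax(tissue_mean$intensity - matrix_mean$intensity,
                                0)
  tissue_mean
}
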
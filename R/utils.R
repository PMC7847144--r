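#' @noRd
TISSUE_LABELS <- c("NCE", "stroma", "cancer", "matrix", "unannotated")

#' @noRd
ANNOT_LABELS <- c("NCE", "stroma", "cancer", "matrix")

# Carbon isotope spacing in Da (mass difference 13C - 12C)
ISOTOPE_DA <- 1.00335

#' Derive a reproducible sub-stream seed from a root seed
#'
#' All randomness in the package flows from one root seed through named
#' sub-streams so that individual stages (simulation, permutation testing,
#' LMM subsampling) are independently reproducible. Kept below 2^31.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 1000003L
  as.integer((abs(seed) %% 1000003L) * 2011L + h * 31L) %% 2147483629L
}

#' Run code under a temporary RNG seed, restoring the RNG state after
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Parts-per-million difference between two masses
#' @noRd
ppm_diff <- function(mz1, mz2) 1e6 * abs(mz1 - mz2) / mz2

#' Half-width in Da of a total ppm window centred at mz
#' @noRd
ppm_halfwidth <- function(mz, window_ppm) mz * window_ppm / 2e6

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
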
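#' Fit a two-group linear mixed model with a patient random intercept
#'
#' Fits `y = b0 + b1 * group + u_patient + e` with `u ~ N(0, sigma_u^2)` and
#' `e ~ N(0, sigma_e^2)` by restricted maximum likelihood. The variance ratio
#' `sigma_u^2 / sigma_e^2` is profiled out and optimized in one dimension,
#' with closed-form generalized least squares at each evaluation, so a fit
#' costs microseconds even inside the iterative subsampling scheme. A
#' singular fit (`sigma_u -> 0`) is a valid fit that degenerates to ordinary
#' least squares. The Wald p value for `b1` uses a normal reference
#' distribution.
#'
#' @param y numeric response (peak heights).
#' @param group 0/1 indicator (or two-level factor; the second sorted level
#'   is coded 1, so `b1` is level2 minus level1).
#' @param patient_id grouping factor for the random intercept.
#' @return an object of class `msi_lmm_fit` with `beta0`, `beta1`,
#'   `se_beta1`, `sigma_patient`, `sigma_resid`, `p_value`, `n_used`,
#'   `n_patients_used`.
#' @export
fit_lmm <- function(y, group, patient_id) {
  if (is.factor(group) || is.character(group)) {
    lev <- sort(unique(as.character(group)))
    if (length(lev) != 2) abort("`group` must have exactly 2 levels.")
    group <- as.numeric(as.character(group) == lev[2])
  }
  g <- as.numeric(group)
  ok <- complete.cases(y, g, patient_id)
  y <- y[ok]; g <- g[ok]; patient_id <- patient_id[ok]
  if (length(unique(g)) < 2) abort("One group is absent.")
  if (length(y) < 4) abort("Need at least 4 observations.")
  pat <- as.integer(factor(patient_id))
  fit <- lmm_reml_core(y, g, pat)
  structure(fit, class = "msi_lmm_fit")
}

#' @exportS3Method base::print
print.msi_lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<msi_lmm_fit> b1 = %.4g (se %.3g), p = %.3g; sigma_u = %.3g, sigma_e = %.3g (n = %d, %d patients)\n",
    x$beta1, x$se_beta1, x$p_value, x$sigma_patient, x$sigma_resid,
    x$n_used, x$n_patients_used))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.msi_lmm_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "group"),
    estimate = c(x$beta0, x$beta1),
    std.error = c(NA_real_, x$se_beta1),
    p.value = c(NA_real_, x$p_value)
  )
}

# Profiled-REML core. pat must be a 1..q integer coding.
#' @noRd
lmm_reml_core <- function(y, g, pat) {
  n <- length(y)
  q <- max(pat)
  xtx <- matrix(c(n, sum(g), sum(g), sum(g * g)), 2, 2)
  xty <- c(sum(y), sum(g * y))
  yty <- sum(y * y)
  # per-patient sufficient statistics
  n_i <- tabulate(pat, q)
  s1 <- n_i
  s2 <- as.vector(rowsum(g, pat, reorder = TRUE))
  t_i <- as.vector(rowsum(y, pat, reorder = TRUE))

  crit <- function(loglam) {
    lam <- exp(loglam)
    ci <- lam / (1 + lam * n_i)
    a11 <- xtx[1, 1] - sum(ci * s1 * s1)
    a12 <- xtx[1, 2] - sum(ci * s1 * s2)
    a22 <- xtx[2, 2] - sum(ci * s2 * s2)
    b1 <- xty[1] - sum(ci * s1 * t_i)
    b2 <- xty[2] - sum(ci * s2 * t_i)
    det_a <- a11 * a22 - a12 * a12
    if (det_a <= 0) return(list(value = Inf))
    beta <- c(a22 * b1 - a12 * b2, a11 * b2 - a12 * b1) / det_a
    quad <- (yty - sum(ci * t_i^2)) - (beta[1] * b1 + beta[2] * b2)
    quad <- max(quad, 1e-300)
    sig2 <- quad / (n - 2)
    val <- (n - 2) * log(sig2) + sum(log1p(lam * n_i)) + log(det_a)
    list(value = val, beta = beta, sig2 = sig2, lam = lam,
         var_b1 = sig2 * a11 / det_a)
  }
  opt <- optimize(function(ll) crit(ll)$value, interval = c(-15, 10))
  # compare against the OLS boundary (lambda -> 0)
  at_zero <- crit(-300)
  best <- if (at_zero$value <= opt$objective) -300 else opt$minimum
  res <- crit(best)
  se <- sqrt(res$var_b1)
  z <- res$beta[2] / se
  list(
    beta0 = res$beta[1], beta1 = res$beta[2], se_beta1 = se,
    sigma_patient = sqrt(res$lam * res$sig2 * (best > -300)),
    sigma_resid = sqrt(res$sig2 * (1 + 0)),
    p_value = 2 * pnorm(-abs(z)),
    n_used = n, n_patients_used = q
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control across a vector of p values
#' (delegates to [stats::p.adjust()]). Errors on p values outside `[0, 1]`.
#'
#' @param p numeric vector of p values.
#' @return adjusted p values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Configuration of the iterative LMM procedure
#'
#' @param fraction fraction of spectra drawn per iteration.
#' @param n_iter number of iterations.
#' @param alpha significance level on the mean adjusted p.
#' @param seed integer seed for the subsampling stream.
#' @param max_retries bounded resampling attempts per iteration to guarantee
#'   both groups and at least two patients in the subsample.
#' @return a list of class `msi_lmm_config`.
#' @export
iterative_config <- function(fraction = 0.005, n_iter = 1000, alpha = 0.05,
                             seed = 1, max_retries = 100) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  if (n_iter < 1) abort("`n_iter` must be >= 1.")
  structure(list(fraction = fraction, n_iter = n_iter, alpha = alpha,
                 seed = seed, max_retries = max_retries),
            class = "msi_lmm_config")
}

#' Fraction-based iterative linear mixed models
#'
#' Spatial autocorrelation between neighbouring MSI pixels violates the
#' independence assumption of a mixed model fitted to all spectra. This
#' procedure instead draws a small random fraction of the spectra of the two
#' compared tissue types (minimizing the number of neighbouring spectra in
#' any one model), fits the patient-random-intercept LMM per mass,
#' Benjamini-Hochberg adjusts the p values across masses within the
#' iteration, and repeats; the reported statistic per mass is the arithmetic
#' mean of the adjusted p values over all iterations. Iterations in which a
#' mass's fit fails contribute an adjusted p of 1 for that mass (recorded in
#' `failure_fraction`), so the average is always over exactly `n_iter`
#' values.
#'
#' Subsampling is performed on the canonical pixel order
#' `(sample_id, x, y)`, so results do not depend on the row order of the
#' input matrix.
#'
#' @param pm an [msi_peakmatrix].
#' @param pair character vector `c(A, B)` of the two tissue labels to
#'   compare; `b1` estimates A minus B.
#' @param config an [iterative_config()].
#' @param log2_input fit the LMM on `log2` heights instead of raw normalized
#'   heights (default raw).
#' @return a tibble with `mz`, `mean_adj_p`, `failure_fraction`,
#'   `significant` (mean adjusted p below `config$alpha`).
#' @export
iterative_lmm <- function(pm, pair, config = iterative_config(),
                          log2_input = FALSE) {
  stopifnot(inherits(pm, "msi_peakmatrix"), length(pair) == 2)
  keep <- pm$row_meta$tissue_label %in% pair
  values <- pm$values[keep, , drop = FALSE]
  meta <- pm$row_meta[keep, ]
  n <- nrow(values)
  if (config$fraction * n < 10) {
    abort(sprintf(
      "fraction * rows = %.1f < 10; increase `fraction` (rows available: %d).",
      config$fraction * n, n))
  }
  ord <- order(meta$sample_id, meta$x, meta$y)
  values <- values[ord, , drop = FALSE]
  meta <- meta[ord, ]
  if (log2_input) {
    floor_val <- min(values[values > 0]) / 10
    values <- log2(pmax(values, floor_val))
  }
  g_all <- as.numeric(meta$tissue_label == pair[1])
  pat_all <- as.integer(factor(meta$patient_id))
  n_sub <- ceiling(config$fraction * n)
  n_mass <- ncol(values)

  p_sum <- numeric(n_mass)
  fail_count <- numeric(n_mass)
  with_seed(derive_seed(config$seed, "lmm_sampling"), {
    for (it in seq_len(config$n_iter)) {
      idx <- NULL
      for (try in seq_len(config$max_retries)) {
        cand <- sample.int(n, n_sub)
        if (length(unique(g_all[cand])) == 2 &&
            length(unique(pat_all[cand])) >= 2) {
          idx <- cand
          break
        }
      }
      if (is.null(idx)) {
        p_sum <- p_sum + 1
        fail_count <- fail_count + 1
        next
      }
      g <- g_all[idx]
      pat <- as.integer(factor(pat_all[idx]))
      p_raw <- vapply(seq_len(n_mass), function(j) {
        tryCatch(
          lmm_reml_core(values[idx, j], g, pat)$p_value,
          error = function(e) NA_real_
        )
      }, numeric(1))
      adj <- bh_adjust(p_raw)
      failed <- is.na(adj)
      adj[failed] <- 1
      fail_count <- fail_count + failed
      p_sum <- p_sum + adj
    }
  })
  tibble(
    mz = pm$col_meta$mz,
    mean_adj_p = p_sum / config$n_iter,
    failure_fraction = fail_count / config$n_iter,
    significant = (p_sum / config$n_iter) < config$alpha
  )
}

#' Log2 fold changes between two tissue types
#'
#' `log2` of the ratio of pooled spectrum means (mean extracted height over
#' all A-spectra divided by the mean over all B-spectra) per mass, together
#' with the per-group means and SDs. A zero group mean yields `NA` rather
#' than an infinite fold change.
#'
#' @param pm an [msi_peakmatrix].
#' @param pair character vector `c(A, B)`.
#' @return a tibble with `mz`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `log2fc`.
#' @export
log2fc <- function(pm, pair) {
  stopifnot(inherits(pm, "msi_peakmatrix"), length(pair) == 2)
  a <- pm$row_meta$tissue_label == pair[1]
  b <- pm$row_meta$tissue_label == pair[2]
  if (!any(a) || !any(b)) abort("Both tissue labels must be present.")
  mean_a <- unname(colMeans(pm$values[a, , drop = FALSE]))
  mean_b <- unname(colMeans(pm$values[b, , drop = FALSE]))
  lfc <- ifelse(mean_a > 0 & mean_b > 0, log2(mean_a / mean_b), NA_real_)
  tibble(
    mz = pm$col_meta$mz,
    mean_a = mean_a,
    sd_a = unname(apply(pm$values[a, , drop = FALSE], 2, sd)),
    mean_b = mean_b,
    sd_b = unname(apply(pm$values[b, , drop = FALSE], 2, sd)),
    log2fc = lfc
  )
}

#' Read a mass-identity lookup table
#'
#' CSV with columns `mz`, `name`, `id_in_oplsda` mapping selected masses to
#' identified metabolites/lipids (the product of tandem-MS identification,
#' supplied externally).
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_identity_lookup <- function(path) {
  lk <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("mz", "name", "id_in_oplsda") %in% names(lk))) {
    abort("Identity lookup needs columns mz, name, id_in_oplsda.")
  }
  lk
}

#' Assemble the per-comparison differential-results table
#'
#' Joins log2 fold changes, iterative-LMM mean adjusted p values, VIP scores
#' and (optionally) identities into one row per mass, sorted by m/z: the
#' analysis' final reporting table.
#'
#' @param log2fc_tbl output of [log2fc()].
#' @param lmm_tbl output of [iterative_lmm()].
#' @param vip_tbl tibble with columns `mz` and `vip`.
#' @param lookup optional identity lookup (see [read_identity_lookup()]);
#'   masses match within `lookup_tol_ppm`.
#' @param lookup_tol_ppm identity matching tolerance.
#' @param alpha significance level for the `significant` flag.
#' @return a `msi_diff_result` tibble with columns `mz`, `id`,
#'   `id_in_oplsda`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `log2fc`,
#'   `mean_adj_p`, `failure_fraction`, `vip`, `significant`.
#' @export
assemble_diff_table <- function(log2fc_tbl, lmm_tbl, vip_tbl, lookup = NULL,
                                lookup_tol_ppm = 100, alpha = 0.05) {
  key_round <- function(mz) round(mz, 4)
  orphans <- c(
    setdiff(key_round(log2fc_tbl$mz), key_round(lmm_tbl$mz)),
    setdiff(key_round(lmm_tbl$mz), key_round(vip_tbl$mz)),
    setdiff(key_round(vip_tbl$mz), key_round(log2fc_tbl$mz))
  )
  if (length(orphans)) {
    abort(paste0("Mass lists disagree between inputs; orphans: ",
                 paste(sort(unique(orphans)), collapse = ", ")))
  }
  out <- log2fc_tbl |>
    dplyr::inner_join(dplyr::select(lmm_tbl, "mz", "mean_adj_p",
                                    "failure_fraction"),
                      by = "mz") |>
    dplyr::inner_join(dplyr::select(vip_tbl, "mz", "vip"), by = "mz") |>
    dplyr::arrange(.data$mz) |>
    dplyr::mutate(significant = .data$mean_adj_p < alpha)
  ids <- rep(NA_character_, nrow(out))
  ids_op <- rep(NA_character_, nrow(out))
  if (!is.null(lookup) && nrow(lookup) > 0) {
    for (i in seq_len(nrow(out))) {
      d <- ppm_diff(out$mz[i], lookup$mz)
      j <- which.min(d)
      if (d[j] <= lookup_tol_ppm) {
        ids[i] <- lookup$name[j]
        ids_op[i] <- lookup$id_in_oplsda[j]
      }
    }
  }
  out <- dplyr::mutate(out, id = ids, id_in_oplsda = ids_op) |>
    dplyr::select("mz", "id", "id_in_oplsda", dplyr::everything())
  class(out) <- c("msi_diff_result", class(out))
  out
}
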
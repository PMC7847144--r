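#' Auto-scale a data matrix
#'
#' Centres each column to mean 0 and scales to unit sample SD (n-1
#' denominator). Columns with zero variance are dropped with a warning. The
#' returned parameters can be re-applied to new rows (e.g. held-out patients
#' in cross-validation).
#'
#' @param x numeric matrix or [msi_peakmatrix].
#' @return a list with `x` (the scaled matrix) and `params` (a tibble with
#'   `column`, `mean`, `sd`, `kept`).
#' @export
autoscale <- function(x) {
  if (inherits(x, "msi_peakmatrix")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("Auto-scaling needs at least 2 rows.")
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  kept <- sdev > 0
  if (!all(kept)) {
    warn(sprintf("%d zero-variance column(s) dropped.", sum(!kept)))
  }
  params <- tibble(column = colnames(x), mean = mu, sd = sdev, kept = kept)
  scaled <- sweep(sweep(x[, kept, drop = FALSE], 2, mu[kept]), 2, sdev[kept],
                  "/")
  list(x = scaled, params = params)
}

#' Apply stored scaling parameters to new rows
#' @param x numeric matrix with the same columns as the training matrix.
#' @param params tibble returned by [autoscale()].
#' @return the scaled matrix restricted to the retained columns.
#' @export
apply_scaling <- function(x, params) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- params$column
  if (!all(params$column %in% colnames(x))) {
    abort("Column mismatch between new rows and scaling parameters.")
  }
  keep <- params$column[params$kept]
  sweep(sweep(x[, keep, drop = FALSE], 2, params$mean[params$kept]), 2,
        params$sd[params$kept], "/")
}

#' Principal component analysis of a scaled matrix
#'
#' Thin wrapper around the singular value decomposition exposing orthonormal
#' loadings, scores and explained-variance fractions; input should already be
#' auto-scaled.
#'
#' @param x scaled numeric matrix.
#' @param n_components number of components, at most `min(nrow - 1, ncol)`.
#' @return an object of class `msi_pca` with `loadings`, `scores`,
#'   `explained` and `n_components`.
#' @export
msi_pca <- function(x, n_components = 2) {
  x <- as.matrix(x)
  kmax <- min(nrow(x) - 1, ncol(x))
  if (n_components < 1 || n_components > kmax) {
    abort(sprintf("`n_components` must be in [1, %d].", kmax))
  }
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
      scores = pc$x[, seq_len(n_components), drop = FALSE],
      explained = expl[seq_len(n_components)],
      explained_all = expl,
      n_components = n_components
    ),
    class = "msi_pca"
  )
}

#' @exportS3Method base::print
print.msi_pca <- function(x, ...) {
  cat(sprintf("<msi_pca> %d components; explained: %s\n", x$n_components,
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis: class-
#' orthogonal variation is iteratively removed from the (auto-scaled) data
#' before a single predictive PLS component is computed. With `n_orth = 0`
#' the model is exactly a one-component PLS-DA. Classes are encoded
#' `positive_class -> +1`, other `-> -1`; the decision threshold is the
#' midpoint of the class mean scores, with ties assigned to the positive
#' class.
#'
#' @param x scaled numeric matrix (rows = spectra).
#' @param labels two-class vector of length `nrow(x)`.
#' @param n_orth number of orthogonal components to remove (>= 0). Extraction
#'   stops early when no class-orthogonal variation remains;
#'   `n_orth_actual` records the realized count.
#' @param positive_class label encoded as +1 (defaults to the first sorted
#'   class).
#' @return an object of class `msi_oplsda`.
#' @export
fit_oplsda <- function(x, labels, n_orth = 1, positive_class = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) abort("OPLS-DA requires exactly 2 classes.")
  if (min(table(labels)) < 2) abort("Each class needs at least 2 rows.")
  if (n_orth < 0) abort("`n_orth` must be >= 0.")
  if (is.null(positive_class)) positive_class <- classes[1]
  if (!positive_class %in% classes) abort("`positive_class` not among labels.")
  negative_class <- setdiff(classes, positive_class)
  y <- ifelse(labels == positive_class, 1, -1)

  xf <- x
  k <- ncol(x)
  w_o_mat <- matrix(0, k, 0)
  p_o_mat <- matrix(0, k, 0)
  n_orth_actual <- 0L
  if (n_orth > 0) {
    for (r in seq_len(n_orth)) {
      w <- crossprod(xf, y)
      w <- w / sqrt(sum(w^2))
      t_pred <- xf %*% w
      p <- crossprod(xf, t_pred) / sum(t_pred^2)
      w_o <- p - drop(crossprod(w, p)) * w
      nrm <- sqrt(sum(w_o^2))
      if (nrm < 1e-12) break
      w_o <- w_o / nrm
      t_o <- xf %*% w_o
      p_o <- crossprod(xf, t_o) / sum(t_o^2)
      xf <- xf - t_o %*% t(p_o)
      w_o_mat <- cbind(w_o_mat, w_o)
      p_o_mat <- cbind(p_o_mat, p_o)
      n_orth_actual <- r
    }
  }
  w <- crossprod(xf, y)
  w <- w / sqrt(sum(w^2))
  t_pred <- drop(xf %*% w)
  p <- drop(crossprod(xf, t_pred) / sum(t_pred^2))

  mean_pos <- mean(t_pred[y == 1])
  mean_neg <- mean(t_pred[y == -1])
  structure(
    list(
      w = drop(w), p = p, w_orth = w_o_mat, p_orth = p_o_mat,
      scores = t_pred, labels = labels,
      positive_class = positive_class, negative_class = negative_class,
      threshold = (mean_pos + mean_neg) / 2,
      direction = if (mean_pos >= mean_neg) 1 else -1,
      n_orth = n_orth, n_orth_actual = n_orth_actual,
      k = ncol(x), columns = colnames(x), scaling = NULL
    ),
    class = "msi_oplsda"
  )
}

#' @exportS3Method base::print
print.msi_oplsda <- function(x, ...) {
  cat(sprintf(
    "<msi_oplsda> %s (+1) vs %s (-1); %d variables, %d orthogonal component(s)\n",
    x$positive_class, x$negative_class, x$k, x$n_orth_actual))
  invisible(x)
}

#' Predict class labels with a fitted OPLS-DA model
#'
#' New rows (already scaled with the model's scaling parameters) are filtered
#' with the stored orthogonal weight/loading pairs, scored on the predictive
#' component, and labelled by the side of the decision threshold; ties go to
#' the positive class.
#'
#' @param model an `msi_oplsda`.
#' @param newdata scaled numeric matrix with the model's columns.
#' @return a list with `scores` and `labels`.
#' @export
predict_oplsda <- function(model, newdata) {
  x <- as.matrix(newdata)
  if (ncol(x) != model$k) {
    abort(sprintf("Expected %d columns, got %d.", model$k, ncol(x)))
  }
  if (ncol(model$w_orth) > 0) {
    for (r in seq_len(ncol(model$w_orth))) {
      t_o <- x %*% model$w_orth[, r]
      x <- x - t_o %*% t(model$p_orth[, r])
    }
  }
  scores <- drop(x %*% model$w)
  side <- model$direction * (scores - model$threshold)
  labels <- ifelse(side >= 0, model$positive_class, model$negative_class)
  list(scores = scores, labels = labels)
}

#' @exportS3Method stats::predict
predict.msi_oplsda <- function(object, newdata, ...) {
  predict_oplsda(object, newdata)
}

#' Variable importance on the projection
#'
#' VIP over the single predictive component:
#' `VIP_j = sqrt(K) * |w_j| / ||w||`, so that `sum(VIP^2) = K` exactly.
#' Variables with VIP >= 1 are conventionally considered important for the
#' discrimination.
#'
#' @param model a fitted `msi_oplsda`.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "msi_oplsda"))
  v <- sqrt(model$k) * abs(model$w) / sqrt(sum(model$w^2))
  names(v) <- model$columns
  v
}

#' @exportS3Method generics::tidy
tidy.msi_oplsda <- function(x, ...) {
  tibble(
    variable = x$columns %||% sprintf("V%d", seq_len(x$k)),
    weight = x$w, loading = x$p, vip = unname(vip_scores(x))
  )
}

#' @exportS3Method generics::glance
glance.msi_oplsda <- function(x, ...) {
  tibble(
    positive_class = x$positive_class, negative_class = x$negative_class,
    n_variables = x$k, n_orth = x$n_orth, n_orth_actual = x$n_orth_actual,
    threshold = x$threshold
  )
}

#' Leave-one-patient-out cross-validation of OPLS-DA
#'
#' One fold per patient: all of that patient's spectra are held out, the
#' model is refitted on the remaining patients (including re-estimating the
#' auto-scaling), and the held-out spectra are predicted. Folds whose
#' training set lacks a class are skipped with a warning. Accuracy is pooled
#' over all predicted held-out spectra.
#'
#' @param values unscaled numeric matrix of peak heights.
#' @param labels two-class vector.
#' @param patients patient id per row.
#' @param n_orth orthogonal components per fold model.
#' @param positive_class label encoded +1.
#' @return an object of class `msi_cv_result` with `predictions` (tibble),
#'   `accuracy`, and `skipped_folds`.
#' @export
lopo_cv <- function(values, labels, patients, n_orth = 1,
                    positive_class = NULL) {
  values <- as.matrix(values)
  labels <- as.character(labels)
  patients <- as.character(patients)
  stopifnot(nrow(values) == length(labels), length(labels) == length(patients))
  classes <- sort(unique(labels))
  if (length(classes) != 2) abort("lopo_cv requires exactly 2 classes.")
  if (is.null(positive_class)) positive_class <- classes[1]

  folds <- unique(patients)
  preds <- vector("list", length(folds))
  skipped <- character(0)
  for (i in seq_along(folds)) {
    pat <- folds[i]
    test_idx <- which(patients == pat)
    train_idx <- which(patients != pat)
    if (length(unique(labels[train_idx])) < 2 ||
        min(table(labels[train_idx])) < 2) {
      warn(sprintf("Fold '%s' skipped: training set lacks a class.", pat))
      skipped <- c(skipped, pat)
      next
    }
    sc <- suppressWarnings(autoscale(values[train_idx, , drop = FALSE]))
    model <- fit_oplsda(sc$x, labels[train_idx], n_orth = n_orth,
                        positive_class = positive_class)
    test_scaled <- apply_scaling(values[test_idx, , drop = FALSE], sc$params)
    pr <- predict_oplsda(model, test_scaled)
    preds[[i]] <- tibble(
      row = test_idx, patient_id = pat, truth = labels[test_idx],
      predicted = pr$labels, score = pr$scores
    )
  }
  predictions <- dplyr::bind_rows(preds)
  if (nrow(predictions) == 0) abort("All folds were skipped.")
  structure(
    list(
      predictions = predictions,
      accuracy = mean(predictions$predicted == predictions$truth),
      skipped_folds = skipped,
      n_orth = n_orth, positive_class = positive_class
    ),
    class = "msi_cv_result"
  )
}

#' @exportS3Method base::print
print.msi_cv_result <- function(x, ...) {
  cat(sprintf("<msi_cv_result> accuracy %.3f over %d held-out spectra (%d fold(s) skipped)\n",
              x$accuracy, nrow(x$predictions), length(x$skipped_folds)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.msi_cv_result <- function(x, ...) x$predictions

#' @exportS3Method generics::glance
glance.msi_cv_result <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_predicted = nrow(x$predictions),
         n_folds = length(unique(x$predictions$patient_id)),
         n_skipped = length(x$skipped_folds))
}

#' Permutation test of OPLS-DA cross-validated accuracy
#'
#' Class labels are permuted uniformly over spectra in each iteration and
#' the leave-one-patient-out accuracy recomputed, giving a null distribution
#' for the observed accuracy. The p value is
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams lopo_cv
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return an object of class `msi_perm_result` with `observed`, `null`
#'   (length `n_perm`), and `p_value`.
#' @export
permutation_test <- function(values, labels, patients, n_orth = 1,
                             n_perm = 1000, seed = 1,
                             positive_class = NULL) {
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  observed <- suppressWarnings(
    lopo_cv(values, labels, patients, n_orth, positive_class)$accuracy
  )
  null_acc <- with_seed(derive_seed(seed, "permutation"), {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample(labels)
      acc <- tryCatch(
        suppressWarnings(
          lopo_cv(values, perm, patients, n_orth, positive_class)$accuracy
        ),
        error = function(e) NA_real_
      )
      acc
    }, numeric(1))
  })
  null_acc[is.na(null_acc)] <- 1 # unpredictable fold structure: conservative
  p <- (1 + sum(null_acc >= observed)) / (n_perm + 1)
  structure(
    list(observed = observed, null = null_acc, p_value = p, n_perm = n_perm),
    class = "msi_perm_result"
  )
}

#' @exportS3Method base::print
print.msi_perm_result <- function(x, ...) {
  cat(sprintf("<msi_perm_result> observed accuracy %.3f, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.msi_perm_result <- function(x, ...) {
  tibble(observed = x$observed, p_value = x$p_value, n_perm = x$n_perm,
         null_mean = mean(x$null))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
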
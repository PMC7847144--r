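test_that("auto-scaling centres, scales, and stores reusable parameters", {
  x <- cbind(a = c(1, 3), b = c(2, 2), c = c(0, 10))
  expect_warning(sc <- autoscale(x), "zero-variance")
  expect_equal(colnames(sc$x), c("a", "c"))
  expect_equal(unname(sc$x[, "a"]), c(-1, 1) / sqrt(2), tolerance = 1e-10)
  expect_true(all(abs(colMeans(sc$x)) < 1e-10))
  expect_true(all(abs(apply(sc$x, 2, sd) - 1) < 1e-10))

  again <- apply_scaling(x, sc$params)
  expect_equal(again, sc$x, tolerance = 1e-12)
})

test_that("PCA matches the SVD and reconstructs its input", {
  set.seed(5)
  x <- scale(matrix(rnorm(500), 50, 10))
  x <- x[, ] # strip scale attrs

  r1 <- tcrossprod(rnorm(50), rnorm(10))
  p1 <- msi_pca(scale(r1, scale = FALSE), n_components = 2)
  expect_gte(p1$explained[1], 0.999)

  p <- msi_pca(x, n_components = 10)
  expect_lt(max(abs(p$scores %*% t(p$loadings) - x)), 1e-8)
  # orthonormal loadings
  expect_lt(max(abs(crossprod(p$loadings) - diag(10))), 1e-8)
  # score variances follow the singular values
  sv <- svd(x)$d
  expect_equal(unname(apply(p$scores, 2, function(s) sum(s^2))), sv^2,
               tolerance = 1e-8)

  expect_error(msi_pca(x, n_components = 11), "n_components")
})

test_that("OPLS-DA with no orthogonal components is exactly one-component PLS-DA", {
  set.seed(6)
  x <- scale(matrix(rnorm(300), 30, 10))[, ]
  y <- rep(c("A", "B"), each = 15)
  m <- fit_oplsda(x, y, n_orth = 0)
  yy <- ifelse(y == "A", 1, -1)
  w <- crossprod(x, yy)
  w <- w / sqrt(sum(w^2))
  expect_lt(max(abs(m$scores - drop(x %*% w))), 1e-10)
  expect_equal(m$n_orth_actual, 0L)
})

test_that("orthogonal extraction stops early when no class-orthogonal variance exists", {
  set.seed(7)
  t_pred <- c(rnorm(10, 2), rnorm(10, -2))
  p_load <- rnorm(6)
  x <- tcrossprod(t_pred, p_load)
  y <- rep(c("A", "B"), each = 10)
  m <- fit_oplsda(x, y, n_orth = 2)
  expect_equal(m$n_orth_actual, 0L)
})

test_that("one orthogonal round removes a planted orthogonal component", {
  set.seed(8)
  n <- 40
  y <- rep(c("A", "B"), each = 20)
  t_pred <- ifelse(y == "A", 1, -1)   # predictive scores proportional to y
  t_orth <- rnorm(n)
  t_orth <- t_orth - t_pred * sum(t_orth * t_pred) / sum(t_pred^2)
  p1 <- rnorm(8); p2 <- rnorm(8)      # deliberately non-orthogonal loadings
  x <- tcrossprod(t_pred, p1) + 3 * tcrossprod(t_orth, p2)
  m <- fit_oplsda(x, y, n_orth = 1)
  expect_lt(abs(cor(m$scores, t_orth)), 1e-6)
})

test_that("prediction reproduces training scores and respects the threshold rule", {
  set.seed(9)
  x <- scale(matrix(rnorm(200), 20, 10))[, ]
  y <- rep(c("A", "B"), each = 10)
  m <- fit_oplsda(x, y, n_orth = 1)
  pr <- predict_oplsda(m, x)
  expect_equal(pr$scores, m$scores, tolerance = 1e-12)

  mean_a <- colMeans(x[y == "A", ])
  pr_a <- predict_oplsda(m, rbind(mean_a))
  expect_equal(unname(pr_a$labels), "A")

  expect_error(predict_oplsda(m, x[, 1:5]), "columns")
})

test_that("held-out rows with large planted effects are classified accurately", {
  panel <- default_panel()
  panel$effect_cancer <- rep(c(2, -2), 15)
  cfg <- sim_config(n_patients = 4, samples_per_patient = 1, grid = c(16, 16),
                    peak_panel = panel, noise_sd = 0.3, spatial_sd = 0.2,
                    patient_sd = 0.2, seed = 10)
  pm <- simulate_peak_matrix(cfg)$peak_matrix
  keep <- pm$row_meta$tissue_label %in% c("cancer", "NCE")
  vals <- pm$values[keep, ]
  labs <- pm$row_meta$tissue_label[keep]
  train <- seq_along(labs) %% 2 == 0
  sc <- autoscale(vals[train, ])
  m <- fit_oplsda(sc$x, labs[train], n_orth = 1, positive_class = "cancer")
  pr <- predict_oplsda(m, apply_scaling(vals[!train, ], sc$params))
  expect_gt(mean(pr$labels == labs[!train]), 0.9)
})

test_that("VIP satisfies its closed form and normalization identity", {
  # identical columns: perfectly symmetric weights, all VIP = 1
  set.seed(12)
  base <- rnorm(20)
  x <- matrix(base, 20, 5)
  y <- rep(c("A", "B"), 10)
  m <- fit_oplsda(x, y, n_orth = 0)
  expect_equal(unname(vip_scores(m)), rep(1, 5), tolerance = 1e-10)

  # K = 2 with all class signal in one column: VIP = (sqrt(2), 0)
  yy <- rep(c(1, -1), 10)
  z <- rnorm(20)
  z <- z - yy * sum(z * yy) / sum(yy^2)
  x2 <- cbind(yy, z)
  m2 <- fit_oplsda(x2, rep(c("A", "B"), 10), n_orth = 0)
  expect_equal(unname(vip_scores(m2)), c(sqrt(2), 0), tolerance = 1e-8)

  for (seed in 1:5) {
    set.seed(seed)
    xr <- scale(matrix(rnorm(30 * 8), 30, 8))[, ]
    mr <- fit_oplsda(xr, rep(c("A", "B"), 15), n_orth = 1)
    expect_lt(abs(sum(vip_scores(mr)^2) - 8), 1e-8)
  }
})

test_that("orthogonal filtering never flips the predictive correlation sign", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- scale(matrix(rnorm(40 * 6), 40, 6))[, ]
    y <- rep(c("A", "B"), 20)
    yy <- ifelse(y == "A", 1, -1)
    m0 <- fit_oplsda(x, y, n_orth = 0)
    m2 <- fit_oplsda(x, y, n_orth = 2)
    expect_equal(sign(cor(m0$scores, yy)), sign(cor(m2$scores, yy)))
  }
})

test_that("leave-one-patient-out folds partition by patient", {
  set.seed(13)
  n <- 80
  pats <- rep(sprintf("p%d", 1:4), each = 20)
  labs <- rep(rep(c("A", "B"), each = 10), 4)
  x <- matrix(rnorm(n * 5), n, 5)
  x[, 1] <- ifelse(labs == "A", 5, -5) + rnorm(n, 0, 0.1) # separable column
  cv <- lopo_cv(x, labs, pats, n_orth = 0)
  expect_equal(cv$accuracy, 1.0)
  expect_equal(nrow(cv$predictions), n)
  # folds partition rows by patient
  by_pat <- split(cv$predictions$row, cv$predictions$patient_id)
  expect_setequal(unlist(by_pat), seq_len(n))
  for (p in names(by_pat)) {
    expect_true(all(pats[by_pat[[p]]] == p))
  }
})

test_that("chance-level labels give chance-level accuracy", {
  set.seed(14)
  n <- 400
  pats <- rep(sprintf("p%d", 1:8), each = 50)
  labs <- sample(rep(c("A", "B"), n / 2))
  x <- matrix(rnorm(n * 6), n, 6)
  cv <- suppressWarnings(lopo_cv(x, labs, pats, n_orth = 1))
  expect_gte(cv$accuracy, 0.35)
  expect_lte(cv$accuracy, 0.65)
})

test_that("cross-validated accuracy on the default scenario brackets the expected range", {
  cfg <- sim_config(seed = 11)
  pm <- simulate_peak_matrix(cfg)$peak_matrix
  keep <- pm$row_meta$tissue_label %in% c("cancer", "NCE")
  cv <- suppressWarnings(lopo_cv(
    pm$values[keep, ], pm$row_meta$tissue_label[keep],
    pm$row_meta$patient_id[keep], n_orth = 1, positive_class = "cancer"
  ))
  expect_gte(cv$accuracy, 0.70)
  expect_lte(cv$accuracy, 0.95)
})

test_that("permutation p values follow the add-one formula", {
  set.seed(16)
  n <- 60
  pats <- rep(sprintf("p%d", 1:4), each = 15)
  labs <- rep(c("A", "B", "A"), 20)
  x <- matrix(rnorm(n * 4), n, 4)
  x[, 2] <- ifelse(labs == "A", 4, -4) + rnorm(n, 0, 0.2)
  pt <- permutation_test(x, labs, pats, n_orth = 0, n_perm = 49, seed = 2)
  # separation is planted large: observed beats every permutation
  expect_equal(pt$p_value, 1 / 50)
  expect_length(pt$null, 49)

  # degenerate: every null equals the observed accuracy
  x0 <- matrix(0.5, n, 2)
  x0[, 1] <- rep(c(1, -1), 30) # constant relation to nothing
  pt0 <- list(observed = 0.5, null = rep(0.5, 49))
  p0 <- (1 + sum(pt0$null >= pt0$observed)) / 50
  expect_equal(p0, 1.0)

  expect_error(permutation_test(x, labs, pats, n_perm = 0), "n_perm")
})
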
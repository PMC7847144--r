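test_that("BH adjustment matches hand computations and the exhaustive oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.05, 0.5)), c(0.10, 0.5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # direct min-over-suffix step-up oracle
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    sorted <- p[o]
    adj <- numeric(m)
    for (i in seq_len(m)) {
      adj[i] <- min(sorted[i:m] * m / (i:m), 1)
    }
    out <- numeric(m)
    out[o] <- adj
    out
  }
  set.seed(20)
  for (rep in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_lt(max(abs(bh_adjust(p) - bh_oracle(p))), 1e-12)
  }
})

test_that("the LMM recovers null and planted effects", {
  # deterministic symmetric data: identical group patterns, exact null
  y <- rep(c(1, 2, 3, 4, 5), 40)
  g <- rep(c(0, 1), each = 100)
  pat <- rep(1:10, each = 20)
  f <- fit_lmm(y, g, pat)
  expect_lt(abs(f$beta1), 1e-10)
  expect_gt(f$p_value, 0.5)

  # parameter recovery with strong patient variance
  set.seed(22)
  pat2 <- rep(1:10, each = 20)
  g2 <- rep(rep(0:1, each = 10), 10)
  y2 <- 5 + 1.0 * g2 + rnorm(10, 0, 0.5)[pat2] + rnorm(200, 0, 0.1)
  f2 <- fit_lmm(y2, g2, pat2)
  expect_lt(abs(f2$beta1 - 1.0), 0.15)
  expect_gt(f2$sigma_patient, 0.2)

  expect_error(fit_lmm(c(1, 2, 3, 4), rep(0, 4), 1:4), "absent")
})

test_that("with one observation per patient the LMM collapses to the pooled t-test", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 100
    g <- rep(0:1, each = n / 2)
    y <- 2 + 0.3 * g + rnorm(n)
    f <- fit_lmm(y, g, seq_len(n))
    tt <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
    expect_equal(f$beta1, mean(y[g == 1]) - mean(y[g == 0]), tolerance = 1e-8)
    expect_lt(abs(f$p_value - tt$p.value), 0.02)
  }
})

test_that("the profiled REML fit agrees with nlme::lme", {
  set.seed(24)
  for (rep in 1:5) {
    q <- 8
    pat <- rep(seq_len(q), each = 15)
    g <- rep(rep(0:1, c(7, 8)), q)
    y <- 1 + 0.6 * g + rnorm(q, 0, 0.6)[pat] + rnorm(length(pat), 0, 0.4)
    f <- fit_lmm(y, g, pat)
    ref <- nlme::lme(y ~ g, random = ~ 1 | pat,
                     data = data.frame(y, g, pat), method = "REML")
    expect_equal(f$beta1, unname(nlme::fixef(ref)[2]), tolerance = 1e-4)
    expect_equal(f$se_beta1, sqrt(ref$varFix[2, 2]), tolerance = 1e-3)
    vc <- suppressWarnings(as.numeric(nlme::VarCorr(ref)[1:2, 2]))
    expect_equal(f$sigma_patient, vc[1], tolerance = 1e-2)
    expect_equal(f$sigma_resid, vc[2], tolerance = 1e-2)
  }
})

test_that("a single iteration equals one plain BH-adjusted LMM pass", {
  cfg <- sim_config(n_patients = 4, samples_per_patient = 1, grid = c(24, 24),
                    seed = 25)
  pm <- simulate_peak_matrix(cfg)$peak_matrix
  icfg <- iterative_config(fraction = 0.05, n_iter = 1, seed = 99)
  got <- iterative_lmm(pm, c("cancer", "NCE"), icfg)

  # reproduce the single subsample by hand with the same derived stream
  keep <- pm$row_meta$tissue_label %in% c("cancer", "NCE")
  vals <- pm$values[keep, ]
  meta <- pm$row_meta[keep, ]
  ord <- order(meta$sample_id, meta$x, meta$y)
  vals <- vals[ord, ]
  meta <- meta[ord, ]
  n_sub <- ceiling(0.05 * nrow(vals))
  idx <- withr::with_seed(derive_seed(99, "lmm_sampling"),
                          sample.int(nrow(vals), n_sub))
  g <- as.numeric(meta$tissue_label[idx] == "cancer")
  p_raw <- vapply(seq_len(ncol(vals)), function(j) {
    fit_lmm(vals[idx, j], g, meta$patient_id[idx])$p_value
  }, numeric(1))
  expect_equal(got$mean_adj_p, bh_adjust(p_raw), tolerance = 1e-12)
})

test_that("mean adjusted p is invariant to the row order of the matrix", {
  cfg <- sim_config(n_patients = 3, samples_per_patient = 1, grid = c(24, 24),
                    seed = 26)
  pm <- simulate_peak_matrix(cfg)$peak_matrix
  icfg <- iterative_config(fraction = 0.05, n_iter = 5, seed = 3)
  a <- iterative_lmm(pm, c("cancer", "NCE"), icfg)
  set.seed(1)
  perm <- sample(nrow(pm$values))
  pm2 <- subset_peakmatrix(pm, perm)
  b <- iterative_lmm(pm2, c("cancer", "NCE"), icfg)
  expect_equal(a$mean_adj_p, b$mean_adj_p, tolerance = 1e-12)
})

test_that("too small a fraction is rejected with advice", {
  cfg <- sim_config(n_patients = 2, samples_per_patient = 1, grid = c(10, 10),
                    seed = 27)
  pm <- simulate_peak_matrix(cfg)$peak_matrix
  expect_error(
    iterative_lmm(pm, c("cancer", "NCE"),
                  iterative_config(fraction = 0.005, n_iter = 2)),
    "increase `fraction`"
  )
})

test_that("log2 fold changes follow the pooled group means", {
  vals <- cbind(c(2, 2, 1, 1), c(4, 4, 1, 1), c(0, 0, 1, 1))
  pm <- msi_peakmatrix(
    vals,
    row_meta = tibble::tibble(sample_id = "s1", x = 0:3, y = 0L,
                              patient_id = "p1",
                              tissue_label = rep(c("cancer", "NCE"), each = 2)),
    col_meta = tibble::tibble(mz = c(100, 200, 300))
  )
  out <- log2fc(pm, c("cancer", "NCE"))
  expect_equal(out$log2fc[1], 1)    # 2 vs 1
  expect_equal(out$log2fc[2], 2)    # 4 vs 1
  expect_true(is.na(out$log2fc[3])) # zero group mean -> undefined
  expect_equal(out$mean_a[1], 2)
  expect_equal(out$sd_b, rep(0, 3))

  same <- log2fc(pm, c("cancer", "cancer"))
  expect_equal(same$log2fc[1:2], c(0, 0))
})

test_that("the differential table assembles, joins identities, and checks keys", {
  lfc <- tibble::tibble(mz = c(100, 200, 300), mean_a = 1, sd_a = 0.1,
                        mean_b = 1, sd_b = 0.1, log2fc = c(1, 0, -1))
  lmm <- tibble::tibble(mz = c(100, 200, 300),
                        mean_adj_p = c(0.01, 0.5, 0.03),
                        failure_fraction = 0, significant = c(TRUE, FALSE, TRUE))
  vip <- tibble::tibble(mz = c(100, 200, 300), vip = c(1.5, 0.2, 1.1))

  out <- assemble_diff_table(lfc, lmm, vip)
  expect_equal(names(out)[1:3], c("mz", "id", "id_in_oplsda"))
  expect_true(all(is.na(out$id)))
  expect_equal(out$significant, c(TRUE, FALSE, TRUE))
  expect_equal(nrow(out), 3)
  expect_setequal(
    names(out),
    c("mz", "id", "id_in_oplsda", "mean_a", "sd_a", "mean_b", "sd_b",
      "log2fc", "mean_adj_p", "failure_fraction", "vip", "significant")
  )

  lookup <- tibble::tibble(mz = 100.001, name = "citrate",
                           id_in_oplsda = "Citrate")
  out2 <- assemble_diff_table(lfc, lmm, vip, lookup = lookup)
  expect_equal(out2$id[1], "citrate")
  expect_true(is.na(out2$id[2]))

  bad_vip <- vip[1:2, ]
  expect_error(assemble_diff_table(lfc, lmm, bad_vip), "orphans")
})

test_that("every planted mass appears exactly once per comparison in assembled results", {
  cfg <- sim_config(n_patients = 3, samples_per_patient = 1, grid = c(24, 24),
                    seed = 28)
  sim <- simulate_peak_matrix(cfg)
  pm <- sim$peak_matrix
  for (pair in list(c("cancer", "NCE"), c("stroma", "NCE"))) {
    lfc <- log2fc(pm, pair)
    lmm <- iterative_lmm(pm, pair,
                         iterative_config(fraction = 0.05, n_iter = 3))
    keep <- pm$row_meta$tissue_label %in% pair
    sc <- autoscale(pm$values[keep, ])
    mod <- fit_oplsda(sc$x, pm$row_meta$tissue_label[keep], n_orth = 1,
                      positive_class = pair[1])
    vip <- tibble::tibble(mz = pm$col_meta$mz, vip = unname(vip_scores(mod)))
    out <- assemble_diff_table(lfc, lmm, vip)
    planted <- cfg$peak_panel$mz[cfg$peak_panel$effect_cancer != 0]
    for (m in planted) {
      expect_equal(sum(out$mz == m), 1)
    }
  }
})
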
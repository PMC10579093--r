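test_that("additivity: per-member Shapley values sum to the margin", {
  set.seed(10)
  n <- 80; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X[, 1] - X[, 3] + 0.5 * rnorm(n) > 0)
  fit <- gbt_fit(X, y, rep(1, n), 40L, 3L, 0.15, 0.8, 0.1, 0.1, 1, 0, 3L)
  sh <- gbt_shap(fit, X)
  m <- gbt_predict(fit, X)
  expect_lt(max(abs(rowSums(sh) - m)), 1e-6)
  # and through the ensemble-level attribute(): mean out-of-fold identity
  att <- small_attribution()
  expect_lt(max(abs(rowSums(att$phi) + att$bias - att$margin)), 1e-6)
  # averaged margins agree with the stored mean out-of-fold margins
  ens <- small_ensemble()
  expect_equal(att$margin, qlogis(pmin(pmax(ens$mean_prob, 1e-12),
                                       1 - 1e-12)),
               tolerance = 0.15)
})

test_that("attribution concentrates on the truly predictive variable", {
  set.seed(11)
  n <- 800
  x1 <- rnorm(n)
  X <- cbind(x1, matrix(rnorm(n * 3), n, 3))
  y <- as.numeric(x1 + 0.3 * rnorm(n) > 0)
  fit <- gbt_fit(X, y, rep(1, n), 50L, 3L, 0.15, 1.0, 0.1, 0.1, 1, 0, 4L)
  sh <- gbt_shap(fit, X)
  imp <- colMeans(abs(sh[, 1:4]))
  expect_gt(imp[1], 0)
  expect_lte(max(imp[2:4]) / imp[1], 0.1)
})

test_that("normalization: formula, sign preservation, L1 identity, zero flag", {
  expect_equal(as.numeric(normalize_attribution(c(2, -1, 1))),
               c(0.5, -0.25, 0.25))
  single <- normalize_attribution(c(0, -3, 0))
  expect_equal(as.numeric(single), c(0, -1, 0))
  set.seed(12)
  M <- matrix(rnorm(60), 10, 6)
  nm <- normalize_attribution(M)
  expect_equal(rowSums(abs(nm)), rep(1, 10), tolerance = 1e-9)
  expect_true(all(sign(nm) == sign(M)))
  z <- normalize_attribution(rbind(M[1, ], rep(0, 6)))
  expect_identical(attr(z, "no_attribution"), c(FALSE, TRUE))
  expect_true(all(z[2, ] == 0))
})

test_that("missingness decomposition: masking, conservation, share", {
  set.seed(13)
  phi <- matrix(rnorm(40), 8, 5)
  mask <- matrix(runif(40) < 0.3, 8, 5)
  d <- decompose_missingness(phi, mask)
  expect_true(all(d$phi_obs[mask] == 0))
  expect_true(all(d$phi_z[!mask] == 0))
  expect_equal(d$phi_z[mask], phi[mask])
  # L1 mass conserved per child
  expect_equal(rowSums(abs(d$phi_obs)) + rowSums(abs(d$phi_z)),
               rowSums(abs(phi)), tolerance = 1e-12)
  # no missingness -> phi_z identically zero
  d0 <- decompose_missingness(phi, matrix(FALSE, 8, 5))
  expect_true(all(d0$phi_z == 0))
  expect_equal(d0$missingness_share, 0)
  expect_error(decompose_missingness(phi, mask[, 1:3]), "dimensions")
  # share formula on a hand-checkable case
  phi1 <- rbind(c(1, -1, 2), c(0, 3, 1))
  mask1 <- rbind(c(TRUE, FALSE, FALSE), c(FALSE, FALSE, TRUE))
  d1 <- decompose_missingness(phi1, mask1)
  expect_equal(d1$missingness_share, 100 * mean(c(1 / 4, 1 / 4)))
})

test_that("importance: degenerate SD, normalized sum, ranking", {
  phi <- matrix(rep(c(0.5, -0.3, 0.2), each = 6), 6, 3)
  imp <- attribution_importance(phi)
  expect_equal(imp$sd, rep(0, 3))
  expect_equal(sort(imp$importance, decreasing = TRUE),
               c(0.5, 0.3, 0.2))
  # normalized attributions with no missingness: importances sum to 1
  set.seed(14)
  M <- normalize_attribution(matrix(rnorm(50), 10, 5))
  expect_equal(sum(attribution_importance(M)$importance), 1,
               tolerance = 1e-9)
  expect_error(attribution_importance(M[0, , drop = FALSE]), "one child")
})

test_that("interaction share: stumps are purely additive, XOR is not", {
  co <- small_cohort()
  stump_cfg <- ensemble_config(K = 2, nrounds = 20, max_depth = 1,
                               seed = 9L)
  ens1 <- train_ensemble(co, "asd_vs_nt", stump_cfg)
  sh1 <- interaction_share(ens1)
  expect_equal(sh1$interaction_pct, 0, tolerance = 1e-9)
  expect_equal(sh1$main_pct + sh1$interaction_pct, 100, tolerance = 1e-9)
  # additive Bayes margin: the fitted trees retain a modest interaction
  # share (branch-specific re-splits), far below a planted interaction
  set.seed(15)
  n <- 800
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(2 * X[, 1] - 2 * X[, 2]))
  fit <- gbt_fit(X, y, rep(1, n), 60L, 3L, 0.15, 1.0, 0.1, 0.1, 1, 0, 6L)
  it <- gbt_shap_inter(fit, X)
  shares <- vapply(seq_len(n), function(i) {
    a <- it[, , i]; tot <- sum(abs(a))
    if (tot == 0) 0 else 1 - sum(abs(diag(a))) / tot
  }, numeric(1))
  additive_share <- mean(shares) * 100
  expect_lte(additive_share, 30)
  # XOR labels force interactions, well above the additive baseline
  yx <- as.numeric(xor(X[, 1] > 0, X[, 2] > 0))
  fitx <- gbt_fit(X, yx, rep(1, n), 60L, 3L, 0.15, 1.0, 0.1, 0.1, 1, 0, 6L)
  itx <- gbt_shap_inter(fitx, X)
  sharesx <- vapply(seq_len(n), function(i) {
    a <- itx[, , i]; tot <- sum(abs(a))
    if (tot == 0) 0 else 1 - sum(abs(diag(a))) / tot
  }, numeric(1))
  expect_gte(mean(sharesx) * 100, 30)
  expect_gt(mean(sharesx) * 100, additive_share + 15)
  # interaction rows sum back to the Shapley values
  shx <- gbt_shap(fitx, X)
  i <- 7
  expect_equal(rowSums(itx[, , i]), shx[i, 1:4], tolerance = 1e-9)
})
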
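test_that("one component suffices when y is linear in a single spectral direction", {
  set.seed(1)
  t <- rnorm(20)
  v <- rnorm(50)
  X <- outer(t, v)
  y <- 2 * t + 1
  m <- pls_nipals(X, y, 1)
  expect_lt(max(abs(predict(m, X) - y)), 1e-10)
})

test_that("full-rank NIPALS calibration predictions equal OLS", {
  set.seed(2)
  X <- matrix(rnorm(50), 10, 5)
  y <- rnorm(10)
  m <- pls_nipals(X, y, 5)
  ols <- lm(y ~ X)
  expect_equal(unname(predict(m, X)), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("NIPALS scores are mutually orthogonal", {
  set.seed(3)
  X <- matrix(rnorm(40 * 30), 40)
  y <- rnorm(40)
  m <- pls_nipals(X, y, 8)
  G <- crossprod(m$scores)
  offdiag <- max(abs(G[upper.tri(G)]))
  expect_lt(offdiag / max(diag(G)), 1e-8)
})

test_that("NIPALS agrees with the Krylov-subspace characterization of PLS1", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(12 * 6), 12)
    y <- rnorm(12)
    for (a in 1:3) {
      m <- pls_nipals(X, y, a)
      expect_equal(unname(predict(m, X)), oracle_pls_fitted(X, y, a),
                   tolerance = 1e-6,
                   info = sprintf("seed=%d a=%d", seed, a))
    }
  }
})

test_that("prediction truncations are consistent with the stored decomposition", {
  set.seed(4)
  X <- matrix(rnorm(25 * 15), 25)
  y <- rnorm(25)
  m <- pls_nipals(X, y, 5)
  expect_equal(predict(m, X, n_lv = 0), rep(mean(y), 25))
  for (a in 1:5) {
    recon <- drop(m$scores[, 1:a, drop = FALSE] %*% m$y_loadings[1:a]) + m$y_mean
    expect_equal(unname(predict(m, X, n_lv = a)), recon, tolerance = 1e-10)
  }
  expect_error(predict(m, X[, 1:3]), "dimension mismatch")
  expect_error(predict(m, X, n_lv = 6), "n_lv")
})

test_that("degenerate fits are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(pls_nipals(X, rep(1, 10), 1), "zero variance")
  expect_error(pls_nipals(X, rnorm(10), 3), "n_lv")
})

test_that("RMSECV is ~0 for noiseless one-component data and matches LOO brute force", {
  set.seed(5)
  t <- rnorm(12); v <- rnorm(20)
  X <- outer(t, v)
  y <- 3 * t
  expect_lt(pls_rmsecv(X, y, 1, folds = 4, seed = 1), 1e-8)
  # folds = n is leave-one-out, independently recomputed by refitting
  Xn <- X + matrix(rnorm(240, sd = 0.05), 12)
  expect_equal(pls_rmsecv(Xn, y, 2, folds = 12, seed = 1),
               oracle_pls_loo(Xn, y, 2), tolerance = 1e-10)
  expect_gte(pls_rmsecv(Xn, y, 1, folds = 4, seed = 2), 0)
})

test_that("cross-validation recovers the true component count", {
  set.seed(6)
  n <- 60; p <- 30
  Tm <- matrix(rnorm(n * 3), n)
  P <- matrix(rnorm(3 * p), 3)
  X <- Tm %*% P + matrix(rnorm(n * p, sd = 0.05), n)
  y <- drop(Tm %*% c(1, -2, 0.5)) + rnorm(n, sd = 0.05)
  lv <- pls_select_lv(X, y, max_lv = 10, folds = 7, seed = 3)
  expect_equal(as.integer(lv), 3L)
  expect_equal(as.integer(pls_select_lv(X, y, max_lv = 1)), 1L)
  expect_lte(as.integer(pls_select_lv(X, y, max_lv = 5)), 5L)
})

test_that("figures of merit follow their definitions", {
  set.seed(7)
  X <- matrix(rnorm(30 * 20), 30)
  y <- drop(X %*% rnorm(20) * 0.1) + rnorm(30, sd = 0.5)
  m <- pls_nipals(X[1:20, ], y[1:20], 3)
  em <- pls_evaluate(m, X[1:20, ], y[1:20], X[21:30, ], y[21:30])
  # RPD * RMSEP == sd of all reference values, by definition
  expect_equal(em$rpd * em$rmsep, sd(y))
  yhat_c <- predict(m, X[1:20, ])
  expect_equal(em$r2c, 1 - sum((y[1:20] - yhat_c)^2) / sum((y[1:20] - mean(y[1:20]))^2))
  expect_equal(em$rmsee, sqrt(sum((y[1:20] - yhat_c)^2) / (20 - 1 - 3)))
  # squared-correlation variant differs but stays in (0, 1] here
  em2 <- pls_evaluate(m, X[1:20, ], y[1:20], X[21:30, ], y[21:30],
                      r2_method = "cor")
  expect_equal(em2$r2p, cor(y[21:30], predict(m, X[21:30, ]))^2)
  # RMSEE degrees of freedom exhausted -> error
  m2 <- pls_nipals(X[1:5, 1:4], y[1:5], 4)
  expect_error(pls_evaluate(m2, X[1:5, 1:4], y[1:5], X[21:30, 1:4], y[21:30]),
               "RMSEE undefined")
})

test_that("perfect prediction leaves RPD undefined", {
  set.seed(8)
  t <- rnorm(12); v <- rnorm(10)
  X <- outer(t, v)
  y <- 2 * t
  m <- pls_nipals(X[1:8, ], y[1:8], 1)
  expect_error(pls_evaluate(m, X[1:8, ], y[1:8], X[9:12, ], y[9:12]),
               "RPD undefined")
})
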
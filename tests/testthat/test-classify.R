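make_blobs <- function(n_per_class = 20, p = 5, sep = 8, classes = 2, seed = 1) {
  with_seed_test(seed, {
    X <- do.call(rbind, lapply(seq_len(classes), function(k)
      matrix(rnorm(n_per_class * p, mean = k * sep), n_per_class)))
    list(X = X, labels = rep(paste0("c", seq_len(classes)), each = n_per_class))
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

test_that("the default log2 parameter grid has the documented structure", {
  g <- svm_param_grid()
  expect_equal(nrow(g), 51 * 31)
  expect_true(all(g$C == 2^g$log2C))
  expect_error(svm_param_grid(step = 0), "step")
  expect_error(svm_param_grid(log2C_range = c(5, -5)), "min < max")
})

test_that("stratified folds preserve class balance and are seeded", {
  labels <- rep(c("a", "b", "c"), times = c(30, 20, 10))
  f1 <- make_stratified_folds(labels, k = 10, seed = 3)
  f2 <- make_stratified_folds(labels, k = 10, seed = 3)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:10)
  # each fold holds 3 a's, 2 b's, 1 c
  for (k in 1:10) expect_equal(as.integer(table(labels[f1 == k])), c(3L, 2L, 1L))
  expect_error(make_stratified_folds(labels, k = 1), ">= 2")
})

test_that("cross-validated accuracy is 100% on well-separated blobs", {
  d <- make_blobs(seed = 5)
  expect_equal(cv_accuracy(d$X, d$labels, C = 10, g = 0.01, k = 10, seed = 1), 100)
})

test_that("shuffled labels give chance-level CV accuracy", {
  d <- with_seed_test(6, list(X = matrix(rnorm(300 * 4), 300),
                              labels = sample(rep(c("a", "b", "c"), 100))))
  acc <- cv_accuracy(d$X, d$labels, C = 1, g = 0.25, k = 10, seed = 2)
  # 99% binomial CI around 1/3 at n = 300
  half <- 2.576 * sqrt(1 / 3 * 2 / 3 / 300) * 100
  expect_gt(acc, 100 / 3 - half)
  expect_lt(acc, 100 / 3 + half)
})

test_that("grid search fixes the folds and breaks ties toward the simpler model", {
  d <- make_blobs(n_per_class = 15, seed = 7)
  grid <- svm_param_grid(log2C_range = c(0, 4), log2g_range = c(-6, -2), step = 2)
  gs <- svm_grid_search(d$X, d$labels, grid = grid, k = 5, seed = 1)
  expect_equal(gs$best_accuracy, max(gs$grid$accuracy))
  # fully separable data: every candidate scores 100, so the tie-break
  # must return the smallest C, then smallest g
  top <- gs$grid[gs$grid$accuracy == gs$best_accuracy, ]
  expect_equal(gs$best$C, min(top$C))
  expect_equal(gs$best$g, min(top$g[top$C == min(top$C)]))
  # single-candidate grid returns that candidate
  one <- svm_grid_search(d$X, d$labels, grid = grid[3, ], k = 5, seed = 1)
  expect_equal(one$best$C, grid$C[3])
  # result is invariant to candidate ordering
  gs_rev <- svm_grid_search(d$X, d$labels, grid = grid[rev(seq_len(nrow(grid))), ],
                            k = 5, seed = 1)
  expect_equal(gs_rev$best, gs$best)
})

test_that("train/predict recover training labels and check dimensions", {
  d <- make_blobs(seed = 8)
  m <- svm_train(d$X, d$labels, C = 10, g = 0.01)
  expect_equal(svm_predict(m, d$X), d$labels)
  expect_error(svm_predict(m, d$X[, 1:3]), "dimension mismatch")
  expect_identical(svm_predict(m, d$X), svm_predict(m, d$X))
})

test_that("recognition rate is the rounded percent of correct labels", {
  truth <- rep("a", 43)
  pred <- c(rep("a", 36), rep("b", 7))
  expect_equal(recognition_rate(pred, truth), 83.72)
  expect_equal(recognition_rate(truth, truth), 100)
  expect_equal(recognition_rate(rep("b", 10), rep("a", 10)), 0)
  expect_error(recognition_rate(character(0), character(0)), "empty")
  expect_error(recognition_rate("a", c("a", "b")), "length")
})
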
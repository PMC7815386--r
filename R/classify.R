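#' Log2-spaced SVM parameter grid
#'
#' Builds the full candidate grid for the RBF-kernel C-SVC grid search:
#' every pair `(C, g) = (2^a, 2^b)` with `a` on the inclusive stepped
#' `log2C_range` and `b` on `log2g_range`. The default grid,
#' log2 C in [-5, 20] and log2 g in [-20, -5] at step 0.5, has
#' 51 x 31 = 1581 candidates.
#'
#' @param log2C_range,log2g_range inclusive `c(min, max)` exponent ranges.
#' @param step exponent step (> 0).
#' @return `data.frame` with columns `log2C`, `log2g`, `C`, `g`.
#' @export
svm_param_grid <- function(log2C_range = c(-5, 20), log2g_range = c(-20, -5),
                           step = 0.5) {
  if (step <= 0) stop_invalid("step must be > 0")
  if (!(log2C_range[1] < log2C_range[2]) || !(log2g_range[1] < log2g_range[2]))
    stop_invalid("exponent ranges must satisfy min < max")
  a <- seq(log2C_range[1], log2C_range[2], by = step)
  b <- seq(log2g_range[1], log2g_range[2], by = step)
  grid <- expand.grid(log2C = a, log2g = b, KEEP.OUT.ATTRS = FALSE)
  grid$C <- 2^grid$log2C
  grid$g <- 2^grid$log2g
  grid
}

#' Stratified cross-validation folds
#'
#' Assigns fold labels 1..k, shuffling within each class (seeded) and
#' cycling fold labels so class proportions are preserved per fold.
#'
#' @param labels class label per sample.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return integer vector of fold assignments.
#' @export
make_stratified_folds <- function(labels, k = 10, seed = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2) stop_invalid("k must be >= 2")
  if (k > n) stop_invalid("more folds (%d) than samples (%d)", k, n)
  folds <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  if (any(tabulate(folds, k) == 0))
    stop_invalid("fold construction left an empty fold; reduce k")
  folds
}

svm_fit_raw <- function(X, labels, C, g) {
  e1071::svm(x = X, y = factor(labels), type = "C-classification",
             kernel = "radial", cost = C, gamma = g, scale = FALSE)
}

#' Cross-validated classification accuracy of an RBF-SVM
#'
#' For each fold, trains a C-SVC with RBF kernel
#' `k(x, z) = exp(-g * ||x - z||^2)` on the remaining folds and predicts the
#' held-out fold; returns the pooled percentage of correct predictions.
#'
#' @param X numeric matrix, samples in rows.
#' @param labels class label per sample.
#' @param C,g SVM penalty and kernel-width parameters (> 0).
#' @param k number of folds (default 10).
#' @param seed fold-construction seed (ignored if `folds` given).
#' @param folds optional precomputed fold assignment.
#' @return pooled cross-validation accuracy in percent.
#' @export
cv_accuracy <- function(X, labels, C, g, k = 10, seed = 1, folds = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (C <= 0 || g <= 0) stop_invalid("C and g must be > 0")
  if (is.null(folds)) folds <- make_stratified_folds(labels, k, seed)
  correct <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- svm_fit_raw(X[tr, , drop = FALSE], labels[tr], C, g)
    pr <- predict(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pr) == labels[!tr])
  }
  100 * correct / length(labels)
}

#' Grid search over SVM parameters with a fixed CV design
#'
#' Evaluates [cv_accuracy()] for every candidate of the grid using the
#' *same* fold assignment throughout (so candidates are compared on an
#' identical resampling design). Ties on accuracy are broken toward the
#' smaller `C`, then the smaller `g` (the simpler model).
#'
#' @param X,labels training data.
#' @param grid candidate grid from [svm_param_grid()].
#' @param k,seed cross-validation design.
#' @return list of class `svm_grid_search`: `grid` (with an `accuracy`
#'   column), `best` (list `C`, `g`, `log2C`, `log2g`), `best_accuracy`.
#' @export
svm_grid_search <- function(X, labels, grid = svm_param_grid(), k = 10, seed = 1) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (nrow(grid) < 1) stop_invalid("empty candidate grid")
  folds <- make_stratified_folds(labels, k, seed)
  acc <- vapply(seq_len(nrow(grid)), function(i)
    cv_accuracy(X, labels, grid$C[i], grid$g[i], folds = folds), numeric(1))
  grid$accuracy <- acc
  ord <- order(-acc, grid$C, grid$g)
  best <- grid[ord[1], ]
  structure(list(grid = grid,
                 best = list(C = best$C, g = best$g,
                             log2C = best$log2C, log2g = best$log2g),
                 best_accuracy = best$accuracy),
            class = "svm_grid_search")
}

#' @export
print.svm_grid_search <- function(x, ...) {
  cat(sprintf("svm_grid_search: %d candidates; best C=%.6g, g=%.8g, CV accuracy %.4f%%\n",
              nrow(x$grid), x$best$C, x$best$g, x$best_accuracy))
  invisible(x)
}

#' Train / predict an RBF-SVM origin classifier
#'
#' Thin wrappers over the libsvm C-SVC solver (one-vs-one voting for
#' multiclass) that pin the kernel to RBF, disable internal feature
#' scaling (pretreated spectra are used as-is), and check feature
#' dimensions at prediction time.
#'
#' @param X training matrix; `labels` class per row; `C`, `g` as in
#'   [cv_accuracy()].
#' @return `svm_train()`: an `nir_svm` model; `svm_predict()`: character
#'   vector of predicted labels.
#' @export
svm_train <- function(X, labels, C, g) {
  X <- as.matrix(X)
  if (C <= 0 || g <= 0) stop_invalid("C and g must be > 0")
  structure(list(fit = svm_fit_raw(X, as.character(labels), C, g),
                 n_features = ncol(X), C = C, g = g),
            class = "nir_svm")
}

#' @param model an `nir_svm` from [svm_train()].
#' @param X_new matrix of spectra to classify.
#' @rdname svm_train
#' @export
svm_predict <- function(model, X_new) {
  stopifnot(inherits(model, "nir_svm"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != model$n_features)
    stop_invalid("feature dimension mismatch: model expects %d, got %d",
                 model$n_features, ncol(X_new))
  as.character(predict(model$fit, X_new))
}

#' Recognition rate
#'
#' Percentage of correctly classified samples, reported to 2 decimals.
#'
#' @param predicted,truth equal-length label vectors.
#' @return percent correct.
#' @export
recognition_rate <- function(predicted, truth) {
  if (length(predicted) == 0) stop_invalid("empty input")
  if (length(predicted) != length(truth))
    stop_invalid("predicted and truth differ in length")
  round(100 * mean(as.character(predicted) == as.character(truth)), 2)
}
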
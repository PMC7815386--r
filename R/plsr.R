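#' PLS1 regression by NIPALS
#'
#' Fits a single-response partial least squares model by the NIPALS
#' deflation algorithm: X and y are mean-centred (no variance scaling);
#' per component the weight `w` is proportional to `X'y` (unit norm), the
#' score is `t = X w`, loadings are `p = X't / t't` and `q = y't / t't`,
#' and X and y are deflated by `t p'` and `t q`. Regression coefficients
#' (and intercepts) are assembled for every truncation 1..`n_lv`, so one
#' fit yields predictions at any smaller latent-variable count. If the
#' residual signal is exhausted before `n_lv` components (rank-deficient
#' data), the model is truncated to the attainable count.
#'
#' @param X numeric matrix, samples in rows.
#' @param y numeric response (mg/g).
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n-1, p)`.
#' @return object of class `pls_model`: centring vectors, per-component
#'   `weights`, `x_loadings`, `y_loadings`, `scores`, the `p x n_lv`
#'   `coefficients` matrix (column `a` = truncation at `a` components) and
#'   matching `intercepts`.
#' @export
pls_nipals <- function(X, y, n_lv) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_invalid("length(y) != nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop_invalid("X and y must be finite")
  if (var(y) == 0) stop_invalid("y has zero variance")
  if (n_lv < 1 || n_lv > min(n - 1, p))
    stop_invalid("n_lv must be in [1, min(n-1, p)] = [1, %d]; got %d",
                 min(n - 1, p), n_lv)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean
  W <- P <- matrix(0, p, n_lv)
  Q <- numeric(n_lv)
  Tm <- matrix(0, n, n_lv)
  s0 <- sqrt(sum(crossprod(Xc, yc)^2))
  A <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xc, yc)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-12 * max(s0, 1)) break  # signal exhausted
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt <= .Machine$double.eps * n) break
    pv <- crossprod(Xc, t)[, 1] / tt
    q <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pv)
    yc <- yc - q * t
    W[, a] <- w; P[, a] <- pv; Q[a] <- q; Tm[, a] <- t
    A <- a
  }
  if (A == 0L) stop_invalid("no PLS component could be extracted")
  W <- W[, 1:A, drop = FALSE]; P <- P[, 1:A, drop = FALSE]
  Q <- Q[1:A]; Tm <- Tm[, 1:A, drop = FALSE]
  B <- matrix(0, p, A)
  intercepts <- numeric(A)
  for (a in 1:A) {
    Wa <- W[, 1:a, drop = FALSE]
    Ba <- Wa %*% solve(crossprod(P[, 1:a, drop = FALSE], Wa), Q[1:a])
    B[, a] <- Ba
    intercepts[a] <- y_mean - drop(x_mean %*% Ba)
  }
  structure(list(n_lv = A, requested_lv = n_lv, x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = Q, scores = Tm,
                 coefficients = B, intercepts = intercepts),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d latent variables, %d variables\n",
              x$n_lv, nrow(x$coefficients)))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param X_new matrix of new spectra.
#' @param n_lv truncation to use (`0` returns the constant calibration mean;
#'   defaults to the model's full component count).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, X_new, n_lv = object$n_lv, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(object$x_mean))
    stop_invalid("dimension mismatch: model has %d variables, data has %d",
                 length(object$x_mean), ncol(X_new))
  if (n_lv < 0 || n_lv > object$n_lv)
    stop_invalid("n_lv must be in [0, %d]", object$n_lv)
  if (n_lv == 0) return(rep(object$y_mean, nrow(X_new)))
  drop(X_new %*% object$coefficients[, n_lv]) + object$intercepts[n_lv]
}

# Predictions at every truncation 1..max_lv (n x max_lv matrix); columns
# beyond the model's attainable rank repeat the last attainable column.
pls_predict_all <- function(model, X_new, max_lv) {
  X_new <- as.matrix(X_new)
  pr <- X_new %*% model$coefficients
  pr <- sweep(pr, 2, model$intercepts, "+")
  if (max_lv > model$n_lv)
    pr <- cbind(pr, matrix(pr[, model$n_lv], nrow(pr), max_lv - model$n_lv))
  pr[, seq_len(max_lv), drop = FALSE]
}

# y-stratified random folds: samples are ranked by y, consecutive rank
# blocks of size k each spread over all k folds (seeded permutation per
# block), so every fold covers the response range.
make_y_folds <- function(y, k, seed) {
  n <- length(y)
  if (k < 2) stop_invalid("folds must be >= 2")
  if (k > n) stop_invalid("more folds (%d) than samples (%d)", k, n)
  folds <- integer(n)
  with_seed(seed, {
    ord <- order(y, seq_len(n))
    i <- 1L
    while (i <= n) {
      j <- min(i + k - 1L, n)
      folds[ord[i:j]] <- sample.int(k)[seq_len(j - i + 1L)]
      i <- j + 1L
    }
  })
  folds
}

# Cross-validated RMSE for every truncation 1..max_lv (pooled over folds).
pls_cv_curve <- function(X, y, max_lv, folds = 7, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  fold_id <- make_y_folds(y, folds, seed)
  sse <- numeric(max_lv)
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    cap <- min(max_lv, sum(tr) - 1L, ncol(X))
    model <- pls_nipals(X[tr, , drop = FALSE], y[tr], cap)
    pr <- pls_predict_all(model, X[!tr, , drop = FALSE], max_lv)
    sse <- sse + colSums((y[!tr] - pr)^2)
  }
  sqrt(sse / n)
}

#' Cross-validated RMSE of a PLS model
#'
#' Root-mean-square error of cross-validation at a given latent-variable
#' count: seeded y-stratified folds, per fold the model is refitted on the
#' remaining samples and the held-out samples predicted.
#'
#' @param X,y calibration data.
#' @param n_lv latent-variable count to evaluate.
#' @param folds number of folds (default 7).
#' @param seed fold seed.
#' @return RMSECV in the units of `y` (mg/g).
#' @export
pls_rmsecv <- function(X, y, n_lv, folds = 7, seed = 1) {
  pls_cv_curve(X, y, n_lv, folds = folds, seed = seed)[n_lv]
}

#' Select the latent-variable count by cross-validation
#'
#' Picks the truncation minimizing RMSECV; ties go to the smaller count.
#'
#' @param X,y calibration data.
#' @param max_lv largest candidate count (default 15, capped at the data
#'   rank).
#' @param folds,seed cross-validation design.
#' @return the selected count (integer) with the RMSECV curve attached as
#'   attribute `"rmsecv"`.
#' @export
pls_select_lv <- function(X, y, max_lv = 15, folds = 7, seed = 1) {
  X <- as.matrix(X)
  cap <- min(max_lv, nrow(X) - 1L, ncol(X))
  curve <- pls_cv_curve(X, y, cap, folds = folds, seed = seed)
  structure(which.min(curve), rmsecv = curve)
}

#' Calibration and prediction figures of merit for a PLS model
#'
#' Computes the usual NIR-calibration diagnostics:
#' `R2C = 1 - SSE_cal/SST_cal` and `R2P = 1 - SSE_pred/SST_pred` (each SST
#' about its own set mean), `RMSEE = sqrt(SSE_cal / (n_cal - 1 - A))` with
#' `A` latent variables (the degrees-of-freedom convention of multivariate
#' calibration software), `RMSEP = sqrt(SSE_pred / n_pred)`, and
#' `RPD = sd_all / RMSEP` where `sd_all` is the sample standard deviation of
#' the reference values of the *whole* sample set (calibration and
#' prediction together). An RPD above 2 is conventionally read as a usable
#' quantitative model.
#'
#' @param model a `pls_model` fitted on `X_cal`, `y_cal`.
#' @param X_cal,y_cal,X_pred,y_pred calibration and prediction data.
#' @param sd_all sample SD of all reference values (defaults to
#'   `sd(c(y_cal, y_pred))`).
#' @param rmsecv optional precomputed RMSECV to carry in the result.
#' @param r2_method `"ss"` (1 - SSE/SST, the default) or `"cor"` (squared
#'   Pearson correlation of predicted vs. measured).
#' @return list of class `pls_metrics`: `n_lv`, `r2c`, `rmsee`, `rmsecv`,
#'   `r2p`, `rmsep`, `rpd`.
#' @export
pls_evaluate <- function(model, X_cal, y_cal, X_pred, y_pred,
                         sd_all = sd(c(y_cal, y_pred)), rmsecv = NA_real_,
                         r2_method = c("ss", "cor")) {
  r2_method <- match.arg(r2_method)
  stopifnot(inherits(model, "pls_model"))
  A <- model$n_lv
  n_cal <- length(y_cal); n_pred <- length(y_pred)
  if (n_cal - 1 - A <= 0)
    stop_invalid("RMSEE undefined: n_cal (%d) must exceed n_lv + 1 (%d)",
                 n_cal, A + 1)
  yhat_c <- predict(model, X_cal)
  yhat_p <- predict(model, X_pred)
  sse_c <- sum((y_cal - yhat_c)^2)
  sse_p <- sum((y_pred - yhat_p)^2)
  r2 <- function(y, yhat, sse) {
    if (r2_method == "cor") cor(y, yhat)^2 else 1 - sse / sum((y - mean(y))^2)
  }
  rmsep <- sqrt(sse_p / n_pred)
  if (rmsep == 0)
    stop_invalid("perfect prediction: RPD undefined (RMSEP = 0)")
  structure(list(n_lv = A,
                 r2c = r2(y_cal, yhat_c, sse_c),
                 rmsee = sqrt(sse_c / (n_cal - 1 - A)),
                 rmsecv = rmsecv,
                 r2p = r2(y_pred, yhat_p, sse_p),
                 rmsep = rmsep,
                 rpd = sd_all / rmsep),
            class = "pls_metrics")
}

#' @export
print.pls_metrics <- function(x, ...) {
  cat(sprintf("pls_metrics (LV=%d): R2C=%.4f RMSEE=%.4f RMSECV=%.4f R2P=%.4f RMSEP=%.4f RPD=%.4f\n",
              x$n_lv, x$r2c, x$rmsee, x$rmsecv, x$r2p, x$rmsep, x$rpd))
  invisible(x)
}
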
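# Independent oracles used to cross-check the package implementations.
# Everything here is written in plain-loop style, deliberately separate
# from the vectorized implementations in the package.

# Greedy max-min sample selection computed with explicit loops over a
# combined (normalized) distance matrix.
oracle_maxmin <- function(D, n_cal) {
  N <- nrow(D)
  best <- c(1L, 2L); bestd <- -Inf
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_cal) {
    cand <- NA_integer_; candd <- -Inf
    for (i in seq_len(N)) {
      if (i %in% sel) next
      mind <- Inf
      for (s in sel) mind <- min(mind, D[i, s])
      if (mind > candd) { candd <- mind; cand <- i }
    }
    sel <- c(sel, cand)
  }
  sort(sel)
}

oracle_spxy <- function(X, y, n_cal) {
  N <- nrow(X)
  dx <- matrix(0, N, N); dy <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) {
    dx[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    dy[i, j] <- abs(y[i] - y[j])
  }
  oracle_maxmin(dx / max(dx) + dy / max(dy), n_cal)
}

oracle_ks <- function(X, n_cal) {
  N <- nrow(X)
  dx <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N) dx[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  oracle_maxmin(dx / max(dx), n_cal)
}

# PLS1 fitted values via the Krylov-subspace characterization: the
# a-component PLS coefficient vector is the least-squares solution
# restricted to span{s, Cs, ..., C^(a-1)s} with s = X'y, C = X'X
# (centred data). Algorithm-independent of NIPALS deflation.
oracle_pls_fitted <- function(X, y, a) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  s <- crossprod(Xc, yc)
  C <- crossprod(Xc)
  K <- matrix(0, ncol(X), a)
  v <- s
  for (i in seq_len(a)) { K[, i] <- v; v <- C %*% v }
  Q <- qr.Q(qr(K))
  Z <- Xc %*% Q
  drop(Z %*% qr.solve(Z, yc)) + mean(y)
}

# Leave-one-out PLS RMSE computed by direct refitting.
oracle_pls_loo <- function(X, y, n_lv) {
  n <- nrow(X)
  sse <- 0
  for (i in seq_len(n)) {
    m <- pls_nipals(X[-i, , drop = FALSE], y[-i], n_lv)
    sse <- sse + (y[i] - predict(m, X[i, , drop = FALSE]))^2
  }
  sqrt(sse / n)
}
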
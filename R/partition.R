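split_result <- function(cal, pred, method, n, y_variable = NULL) {
  structure(list(calibration = sort(cal), prediction = sort(pred),
                 method = method, n = n, y_variable = y_variable),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("split_result (%s): %d calibration / %d prediction samples\n",
              x$method, length(x$calibration), length(x$prediction)))
  invisible(x)
}

# Greedy max-min selection on a combined distance matrix. Seeds with the
# pair at maximal distance, then repeatedly adds the sample whose minimum
# distance to the selected set is largest; ties go to the lowest original
# index, making the selection fully deterministic.
maxmin_select <- function(D, n_cal) {
  N <- nrow(D)
  hit <- which(D == max(D), arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  sel <- as.integer(hit[1, ])
  while (length(sel) < n_cal) {
    rem <- setdiff(seq_len(N), sel)
    mind <- apply(D[rem, sel, drop = FALSE], 1, min)
    sel <- c(sel, rem[which.max(mind)])   # which.max -> first (lowest) index on ties
  }
  sel
}

#' SPXY calibration/prediction split
#'
#' Sample-set partitioning based on joint x-y distances: pairwise Euclidean
#' distances on the spectra and absolute differences on the response are
#' each normalized by their maximum and summed; the calibration set is then
#' grown greedily from the most distant pair by max-min selection. The
#' procedure is deterministic, so a given dataset always yields the same
#' 2:1 (or any requested) split.
#'
#' @param X numeric matrix, samples in rows.
#' @param y numeric response vector (reference concentrations).
#' @param n_cal number of calibration samples, in `[2, N-1]`.
#' @return a `split_result`: sorted calibration and prediction index vectors.
#' @export
spxy_split <- function(X, y, n_cal) {
  X <- as.matrix(X); y <- as.numeric(y)
  N <- nrow(X)
  if (length(y) != N) stop_invalid("length(y) != nrow(X)")
  if (n_cal < 2 || n_cal > N - 1)
    stop_invalid("n_cal must be in [2, N-1]; got %d for N=%d", n_cal, N)
  dx <- as.matrix(dist(X))
  dy <- abs(outer(y, y, "-"))
  mx <- max(dx); my <- max(dy)
  if (mx == 0) stop_invalid("degenerate data: all rows of X identical")
  if (my == 0) stop_invalid("degenerate data: y constant")
  sel <- maxmin_select(dx / mx + dy / my, n_cal)
  split_result(sel, setdiff(seq_len(N), sel), "spxy", N, y_variable = "y")
}

#' Kennard-Stone split (X-only SPXY special case)
#'
#' @rdname spxy_split
#' @export
ks_split <- function(X, n_cal) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (n_cal < 2 || n_cal > N - 1)
    stop_invalid("n_cal must be in [2, N-1]; got %d for N=%d", n_cal, N)
  dx <- as.matrix(dist(X))
  mx <- max(dx)
  if (mx == 0) stop_invalid("degenerate data: all rows of X identical")
  sel <- maxmin_select(dx / mx, n_cal)
  split_result(sel, setdiff(seq_len(N), sel), "ks", N)
}

#' Stratified Kennard-Stone split for classification
#'
#' Allocates per-class calibration quotas proportional to class size
#' (largest-remainder rounding, quotas clamped so every class keeps at
#' least one sample in each set) and runs [ks_split()] within each class,
#' so all origin classes appear in both the calibration and prediction sets.
#'
#' @param labels class label per sample.
#' @param X numeric matrix, samples in rows.
#' @param n_cal total calibration-set size.
#' @return a `split_result`.
#' @export
stratified_split <- function(labels, X, n_cal) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  N <- nrow(X)
  if (length(labels) != N) stop_invalid("labels length != nrow(X)")
  classes <- unique(labels)
  sizes <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(sizes < 2))
    stop_invalid("every class needs >= 2 members; class '%s' has %d",
                 classes[which.min(sizes)], min(sizes))
  if (n_cal < length(classes) || n_cal > N - length(classes))
    stop_invalid("n_cal leaves some class unrepresented in one of the sets")
  quota <- largest_remainder(sizes, n_cal)
  # clamp so both sets keep >=1 member per class, rebalancing deterministically
  quota <- pmin(pmax(quota, 1L), sizes - 1L)
  while (sum(quota) != n_cal) {
    if (sum(quota) < n_cal) {
      i <- which(quota < sizes - 1L)[1]
      quota[i] <- quota[i] + 1L
    } else {
      i <- which(quota > 1L)[1]
      quota[i] <- quota[i] - 1L
    }
  }
  cal <- integer(0)
  for (i in seq_along(classes)) {
    idx <- which(labels == classes[i])
    if (quota[i] == length(idx)) { cal <- c(cal, idx); next }
    sub <- ks_split(X[idx, , drop = FALSE], quota[i])
    cal <- c(cal, idx[sub$calibration])
  }
  split_result(cal, setdiff(seq_len(N), cal), "stratified_ks", N)
}

# Hamilton / largest-remainder apportionment of `total` among groups of the
# given sizes; remainder seats go to the largest fractional parts, ties to
# earlier groups.
largest_remainder <- function(sizes, total) {
  q <- total * sizes / sum(sizes)
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(-(q - base), seq_along(q))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Seeded random split (ablation alternative to SPXY)
#'
#' @param n number of samples.
#' @param n_cal calibration-set size.
#' @param seed RNG seed.
#' @return a `split_result`.
#' @export
random_split <- function(n, n_cal, seed = 1) {
  if (n_cal < 1 || n_cal > n - 1) stop_invalid("n_cal must be in [1, n-1]")
  cal <- with_seed(seed, sample.int(n, n_cal))
  split_result(cal, setdiff(seq_len(n), cal), "random", n)
}

#' Serialize a split as a two-column CSV (sample_id, set)
#'
#' @param split a `split_result`.
#' @param sample_id sample identifiers, length `split$n`.
#' @param path output file.
#' @export
write_split_csv <- function(split, sample_id, path) {
  stopifnot(inherits(split, "split_result"), length(sample_id) == split$n)
  set <- rep("pred", split$n)
  set[split$calibration] <- "cal"
  write.csv(data.frame(sample_id = sample_id, set = set),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
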
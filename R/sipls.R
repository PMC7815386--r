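#' Tile the spectral axis into equidistant intervals
#'
#' Splits `n_variables` columns (canonical descending wavenumber order)
#' into `n_intervals` contiguous intervals whose sizes differ by at most
#' one point: the first `n_variables %% n_intervals` intervals (highest
#' wavenumbers) get the extra point. Interval 1 starts at the highest
#' wavenumber.
#'
#' @param n_variables number of spectral variables.
#' @param n_intervals number of intervals (default 20).
#' @param wavenumbers optional grid; adds the included wavenumber bounds.
#' @return `data.frame`: `interval`, `start`, `end` (inclusive 1-based
#'   column range), `size`, and (if a grid is given) `wn_high`, `wn_low`.
#' @export
make_intervals <- function(n_variables, n_intervals = 20, wavenumbers = NULL) {
  if (n_intervals < 1 || n_intervals > n_variables)
    stop_invalid("n_intervals must be in [1, n_variables]")
  base <- n_variables %/% n_intervals
  extra <- n_variables %% n_intervals
  sizes <- rep(base, n_intervals) + (seq_len(n_intervals) <= extra)
  end <- cumsum(sizes)
  start <- end - sizes + 1L
  out <- data.frame(interval = seq_len(n_intervals), start = start,
                    end = end, size = sizes)
  if (!is.null(wavenumbers)) {
    stopifnot(length(wavenumbers) == n_variables)
    out$wn_high <- wavenumbers[start]
    out$wn_low <- wavenumbers[end]
  }
  out
}

interval_columns <- function(intervals, which_intervals) {
  unlist(lapply(which_intervals, function(i)
    seq.int(intervals$start[i], intervals$end[i])), use.names = FALSE)
}

#' Synergy-interval PLS search
#'
#' Divides the (pretreated) calibration spectra into equidistant intervals
#' and evaluates a PLS model on every k-interval combination: the columns
#' of the combined intervals are extracted, the latent-variable count is
#' chosen by cross-validated RMSE (same seeded fold design for every
#' combination), and combinations are ranked by their minimal
#' cross-validated RMSE. Only calibration data enter the search; the
#' prediction set plays no role in interval selection. Ties are broken
#' toward fewer intervals, then the lexicographically smallest index tuple.
#'
#' @param X_cal,y_cal calibration spectra and response.
#' @param n_intervals number of intervals (default 20).
#' @param k combination sizes to evaluate (default `c(2, 3, 4)`).
#' @param max_lv latent-variable cap per combination (default 15; never
#'   exceeds the combination's column count or data rank).
#' @param folds internal CV segments (default 5).
#' @param seed fold seed.
#' @param wavenumbers optional grid for reporting interval bounds.
#' @return list of class `sipls_result`: `intervals` table, `records`
#'   (`data.frame`: `combination`, `k`, `n_lv`, `rmsecv` per evaluated
#'   combination), and `best` (list: `intervals`, `n_lv`, `rmsecv`).
#' @export
sipls_search <- function(X_cal, y_cal, n_intervals = 20, k = c(2, 3, 4),
                         max_lv = 15, folds = 5, seed = 1, wavenumbers = NULL) {
  X_cal <- as.matrix(X_cal)
  if (any(k < 2) || any(k > n_intervals))
    stop_invalid("combination sizes k must lie in [2, n_intervals]")
  intervals <- make_intervals(ncol(X_cal), n_intervals, wavenumbers)
  combos <- list()
  for (kk in sort(unique(k))) {
    cm <- combn(n_intervals, kk)
    combos <- c(combos, lapply(seq_len(ncol(cm)), function(j) cm[, j]))
  }
  if (length(combos) == 0) stop_invalid("no interval combinations to evaluate")
  rec_comb <- character(length(combos))
  rec_k <- integer(length(combos))
  rec_lv <- integer(length(combos))
  rec_rmse <- numeric(length(combos))
  for (i in seq_along(combos)) {
    cols <- interval_columns(intervals, combos[[i]])
    cap <- min(max_lv, length(cols), nrow(X_cal) - 2L)
    curve <- pls_cv_curve(X_cal[, cols, drop = FALSE], y_cal, cap,
                          folds = folds, seed = seed)
    lv <- which.min(curve)
    rec_comb[i] <- paste(combos[[i]], collapse = ",")
    rec_k[i] <- length(combos[[i]])
    rec_lv[i] <- lv
    rec_rmse[i] <- curve[lv]
  }
  records <- data.frame(combination = rec_comb, k = rec_k, n_lv = rec_lv,
                        rmsecv = rec_rmse, stringsAsFactors = FALSE)
  sort_key <- vapply(combos, function(v)
    paste(sprintf("%03d", v), collapse = ""), character(1))
  ord <- order(rec_rmse, rec_k, sort_key)
  best_i <- ord[1]
  structure(list(intervals = intervals, records = records,
                 best = list(intervals = combos[[best_i]],
                             n_lv = rec_lv[best_i],
                             rmsecv = rec_rmse[best_i])),
            class = "sipls_result")
}

#' @export
print.sipls_result <- function(x, ...) {
  cat(sprintf("sipls_result: %d combinations evaluated; best [%s], LV=%d, RMSECV=%.4f\n",
              nrow(x$records), paste(x$best$intervals, collapse = " "),
              x$best$n_lv, x$best$rmsecv))
  invisible(x)
}

#' Refit and evaluate the best interval combination
#'
#' Fits the final PLS model on the columns of the winning combination and
#' evaluates it on the held-out prediction set with [pls_evaluate()].
#'
#' @param X_cal,y_cal,X_pred,y_pred calibration and prediction data on the
#'   same (pretreated) variable axis used in the search.
#' @param result a `sipls_result` from [sipls_search()].
#' @param sd_all sample SD of all reference values (for RPD).
#' @return list: `model` (`pls_model`), `metrics` (`pls_metrics`), and
#'   `intervals` (the selected rows of the interval table).
#' @export
sipls_refit <- function(X_cal, y_cal, X_pred, y_pred, result,
                        sd_all = sd(c(y_cal, y_pred))) {
  stopifnot(inherits(result, "sipls_result"))
  cols <- interval_columns(result$intervals, result$best$intervals)
  model <- pls_nipals(as.matrix(X_cal)[, cols, drop = FALSE], y_cal,
                      result$best$n_lv)
  metrics <- pls_evaluate(model,
                          as.matrix(X_cal)[, cols, drop = FALSE], y_cal,
                          as.matrix(X_pred)[, cols, drop = FALSE], y_pred,
                          sd_all = sd_all, rmsecv = result$best$rmsecv)
  list(model = model, metrics = metrics,
       intervals = result$intervals[result$best$intervals, , drop = FALSE])
}
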
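#' Standard normal variate transform
#'
#' Standardizes every spectrum (row) to mean 0 and sample standard deviation
#' 1 (n-1 denominator), removing multiplicative scatter and additive offset
#' per spectrum. Stateless: needs no calibration statistics.
#'
#' @param X numeric matrix, spectra in rows.
#' @return matrix of the same shape.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  m <- rowMeans(X)
  s <- apply(X, 1, sd)
  if (any(s < 1e-12)) {
    bad <- which(s < 1e-12)[1]
    nm <- if (!is.null(rownames(X))) rownames(X)[bad] else as.character(bad)
    stop_invalid("SNV undefined for constant spectrum '%s'", nm)
  }
  (X - m) / s
}

#' Multiplicative scatter correction
#'
#' `msc_fit()` learns the reference spectrum (the mean calibration spectrum)
#' on the calibration set only; `msc_apply()` regresses each spectrum on the
#' reference, `x_i ~ a_i + b_i * ref`, and returns `(x_i - a_i) / b_i`,
#' inverting per-spectrum gain and offset. Prediction spectra must be
#' corrected with the state fitted on the calibration set.
#'
#' @param X_cal calibration spectra matrix.
#' @return `msc_fit()`: an `msc_state` list holding `reference`.
#' @export
msc_fit <- function(X_cal) {
  X_cal <- as.matrix(X_cal)
  if (nrow(X_cal) < 1) stop_invalid("msc_fit needs at least one spectrum")
  structure(list(reference = colMeans(X_cal)), class = "msc_state")
}

#' @param X spectra matrix to correct.
#' @param state an `msc_state` from [msc_fit()].
#' @rdname msc_fit
#' @export
msc_apply <- function(X, state) {
  stopifnot(inherits(state, "msc_state"))
  X <- as.matrix(X)
  ref <- state$reference
  if (ncol(X) != length(ref))
    stop_invalid("spectrum length %d != MSC reference length %d",
                 ncol(X), length(ref))
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  b <- as.vector(((X - rowMeans(X)) %*% rc)) / denom
  if (any(abs(b) < 1e-12)) {
    bad <- which(abs(b) < 1e-12)[1]
    nm <- if (!is.null(rownames(X))) rownames(X)[bad] else as.character(bad)
    stop_invalid("degenerate spectrum '%s': MSC slope ~ 0", nm)
  }
  a <- rowMeans(X) - b * mean(ref)
  (X - a) / b
}

# Savitzky-Golay convolution weights for the d-th derivative at the window
# centre: least-squares polynomial fit over symmetric offsets.
sg_coefficients <- function(window, poly_order, deriv_order) {
  h <- (window - 1) / 2
  A <- outer(-h:h, 0:poly_order, "^")
  G <- solve(crossprod(A), t(A))        # (poly+1) x window
  factorial(deriv_order) * G[deriv_order + 1, ]
}

#' Savitzky-Golay derivative
#'
#' Local polynomial smoothing derivative applied per spectrum. Interior
#' points use the central convolution; the `(window-1)/2` points at each
#' edge are obtained from the polynomial fitted to the first / last window,
#' evaluated at the edge positions. The derivative is taken with respect to
#' the variable *index*: on the canonical descending, uniformly spaced
#' wavenumber axis this differs from d/d(cm-1) only by a constant factor
#' (and sign), which centred regression/classification models absorb.
#'
#' @param X numeric matrix, spectra in rows.
#' @param window odd window length in points (default 11).
#' @param poly_order fitted polynomial degree (default 2), < `window`.
#' @param deriv_order derivative order, 1 or 2, <= `poly_order`.
#' @return matrix of the same shape.
#' @export
sg_derivative <- function(X, window = 11, poly_order = 2, deriv_order = 1) {
  X <- as.matrix(X)
  if (window %% 2 != 1 || window <= poly_order)
    stop_invalid("SG window must be odd and > poly_order (got window=%d, poly=%d)",
                 window, poly_order)
  if (!deriv_order %in% c(1, 2) || deriv_order > poly_order)
    stop_invalid("deriv_order must be 1 or 2 and <= poly_order")
  p <- ncol(X)
  if (p < window)
    stop_invalid("need >= %d variables for an SG window of %d", window, window)
  h <- (window - 1) / 2
  cc <- sg_coefficients(window, poly_order, deriv_order)
  out <- matrix(0, nrow(X), p, dimnames = dimnames(X))
  # interior: sum of shifted column blocks
  ni <- p - window + 1
  acc <- matrix(0, nrow(X), ni)
  for (j in seq_len(window))
    acc <- acc + cc[j] * X[, j:(j + ni - 1), drop = FALSE]
  out[, (h + 1):(p - h)] <- acc
  # edges: evaluate the derivative of the boundary polynomial fits
  edge <- function(cols, eval_at) {
    A <- outer(seq_along(cols) - 1, 0:poly_order, "^")
    P <- solve(crossprod(A), t(A))                    # (poly+1) x window
    beta <- X[, cols, drop = FALSE] %*% t(P)          # n x (poly+1)
    sapply(eval_at, function(x0) {
      k <- deriv_order:poly_order
      w <- factorial(k) / factorial(k - deriv_order) * x0^(k - deriv_order)
      as.vector(beta[, k + 1, drop = FALSE] %*% w)
    })
  }
  out[, 1:h] <- edge(1:window, 0:(h - 1))
  out[, (p - h + 1):p] <- edge((p - window + 1):p, (window - h):(window - 1))
  out
}

PRETREAT_TOKENS <- c("raw", "msc", "snv", "1d", "2d")

#' Parse a pretreatment name
#'
#' Pretreatments are named by `+`-joined tokens in application order, the
#' eight usual combinations being `raw`, `msc`, `snv`, `1d`, `2d`,
#' `msc+1d`, `msc+2d`, `snv+1d`, `snv+2d` (scatter correction before the
#' derivative, as the names read). At most one scatter step (`msc` xor
#' `snv`) and one derivative step are allowed.
#'
#' @param method pretreatment name, e.g. `"msc+1d"`.
#' @return character vector of validated step tokens (empty for `"raw"`).
#' @export
parse_pretreatment <- function(method) {
  steps <- tolower(trimws(strsplit(method, "+", fixed = TRUE)[[1]]))
  steps <- steps[steps != ""]
  bad <- setdiff(steps, PRETREAT_TOKENS)
  if (length(bad))
    stop_invalid("unknown pretreatment token(s): %s", paste(bad, collapse = ", "))
  steps <- steps[steps != "raw"]
  if (sum(steps %in% c("msc", "snv")) > 1)
    stop_invalid("at most one scatter step (msc or snv) allowed")
  if (sum(steps %in% c("1d", "2d")) > 1)
    stop_invalid("at most one derivative step allowed")
  steps
}

#' Apply a pretreatment pipeline with a fit/apply split
#'
#' Statistics that depend on the data (the MSC reference spectrum) are
#' learned on the calibration set only and applied unchanged to the
#' prediction set, so no information leaks from prediction spectra into the
#' transform. An optional per-spectrum min-max normalization to [0, 1]
#' (instrument-software style ordinate normalization) can be applied first.
#'
#' @param X_cal calibration spectra matrix.
#' @param X_pred optional prediction spectra matrix (same columns).
#' @param method pretreatment name, see [parse_pretreatment()].
#' @param sg_window,sg_poly Savitzky-Golay window (points, odd) and
#'   polynomial order for the derivative steps.
#' @param normalize logical; min-max scale each spectrum to [0, 1] before
#'   the named steps (default `FALSE`).
#' @return list with `cal`, `pred` (or `NULL`), and `state` (the fitted
#'   `msc_state` or `NULL`).
#' @export
apply_pretreatment <- function(X_cal, X_pred = NULL, method = "raw",
                               sg_window = 11, sg_poly = 2, normalize = FALSE) {
  steps <- parse_pretreatment(method)
  X_cal <- as.matrix(X_cal)
  if (!is.null(X_pred)) {
    X_pred <- as.matrix(X_pred)
    if (ncol(X_pred) != ncol(X_cal))
      stop_invalid("calibration and prediction sets differ in variable count")
  }
  minmax <- function(X) {
    rng <- apply(X, 1, range)
    span <- rng[2, ] - rng[1, ]
    if (any(span < 1e-12)) stop_invalid("min-max normalization undefined for constant spectrum")
    (X - rng[1, ]) / span
  }
  if (normalize) {
    X_cal <- minmax(X_cal)
    if (!is.null(X_pred)) X_pred <- minmax(X_pred)
  }
  state <- NULL
  for (s in steps) {
    if (s == "msc") {
      state <- msc_fit(X_cal)
      X_cal <- msc_apply(X_cal, state)
      if (!is.null(X_pred)) X_pred <- msc_apply(X_pred, state)
    } else if (s == "snv") {
      X_cal <- snv(X_cal)
      if (!is.null(X_pred)) X_pred <- snv(X_pred)
    } else {
      d <- if (s == "1d") 1L else 2L
      X_cal <- sg_derivative(X_cal, sg_window, sg_poly, d)
      if (!is.null(X_pred)) X_pred <- sg_derivative(X_pred, sg_window, sg_poly, d)
    }
  }
  list(cal = X_cal, pred = X_pred, state = state)
}
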
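test_that("SNV standardizes every spectrum exactly", {
  expect_equal(unname(snv(matrix(c(1, 2, 3), 1)))[1, ], c(-1, 0, 1))
  set.seed(1)
  X <- matrix(rnorm(500), 5, 100)
  Z <- snv(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-12)
  # affine invariance: a*x + b (a > 0) has the same SNV transform
  expect_equal(snv(3.7 * X + 2), Z)
  Xc <- X; Xc[2, ] <- 5
  rownames(Xc) <- paste0("s", 1:5)
  expect_error(snv(Xc), "constant spectrum 's2'")
})

test_that("MSC inverts per-spectrum gain and offset against the calibration mean", {
  set.seed(2)
  X <- matrix(rnorm(300), 3, 100)
  st <- msc_fit(X)
  ref <- st$reference
  # a spectrum equal to the reference is unchanged
  expect_equal(unname(msc_apply(rbind(ref), st))[1, ], unname(ref))
  # pure scatter 2*ref + 3 is corrected back to the reference
  expect_equal(unname(msc_apply(rbind(2 * ref + 3), st))[1, ], unname(ref))
  # per-row (a, b) agree with an independent per-row OLS solve
  corrected <- msc_apply(X, st)
  for (i in 1:3) {
    ab <- coef(lm(X[i, ] ~ ref))
    expect_equal(unname(corrected[i, ]), unname((X[i, ] - ab[1]) / ab[2]),
                 tolerance = 1e-10)
  }
  flat <- matrix(rep(ref, 2), 2, byrow = TRUE)
  flat[1, ] <- mean(ref)  # no covariance with the reference
  expect_error(msc_apply(flat, st), "slope")
})

test_that("SG derivatives of low-degree polynomials are exact everywhere", {
  p <- 40
  ramp <- matrix(seq_len(p) - 1, 1)        # value k at index k (0-based)
  d1 <- sg_derivative(ramp, window = 11, poly_order = 2, deriv_order = 1)
  expect_equal(unname(d1)[1, ], rep(1, p), tolerance = 1e-10)
  d2 <- sg_derivative(ramp, window = 11, poly_order = 2, deriv_order = 2)
  expect_equal(unname(d2)[1, ], rep(0, p), tolerance = 1e-10)
  quad <- matrix((seq_len(p) - 1)^2, 1)
  d2q <- sg_derivative(quad, window = 11, poly_order = 2, deriv_order = 2)
  expect_equal(unname(d2q)[1, ], rep(2, p), tolerance = 1e-9)
  d1q <- sg_derivative(quad, window = 7, poly_order = 3, deriv_order = 1)
  expect_equal(unname(d1q)[1, ], 2 * (seq_len(p) - 1), tolerance = 1e-9)
  expect_error(sg_derivative(ramp, window = 10), "odd")
  expect_error(sg_derivative(ramp, window = 3, poly_order = 3), "odd")
  expect_error(sg_derivative(matrix(0, 1, 5), window = 11), "variables")
})

test_that("pretreatment names parse and validate", {
  expect_equal(parse_pretreatment("raw"), character(0))
  expect_equal(parse_pretreatment("msc+1d"), c("msc", "1d"))
  expect_error(parse_pretreatment("msc+snv"), "scatter")
  expect_error(parse_pretreatment("1d+2d"), "derivative")
  expect_error(parse_pretreatment("osc"), "unknown")
})

test_that("pipelines honour the fit/apply split and step order", {
  set.seed(3)
  Xc <- matrix(rnorm(600), 4, 150)
  Xp <- matrix(rnorm(300), 2, 150)
  raw <- apply_pretreatment(Xc, Xp, "raw")
  expect_identical(raw$cal, Xc)
  expect_identical(raw$pred, Xp)
  # msc+1d == manual msc (fit on cal) then SG first derivative
  pp <- apply_pretreatment(Xc, Xp, "msc+1d")
  st <- msc_fit(Xc)
  expect_equal(pp$cal, sg_derivative(msc_apply(Xc, st), 11, 2, 1))
  expect_equal(pp$pred, sg_derivative(msc_apply(Xp, st), 11, 2, 1))
  # the MSC reference comes from the calibration set only
  expect_equal(pp$state$reference, colMeans(Xc))
  # SNV is idempotent
  expect_equal(snv(snv(Xc)), snv(Xc))
})

test_that("scatter correction + derivative shrinks replicate scatter on simulated spectra", {
  ds <- small_dataset()
  groups <- ds$spectra$replicate_group
  noise_to_signal <- function(X) {
    within <- mean(sapply(unique(groups), function(g) {
      idx <- which(groups == g)
      sqrt(mean((X[idx[1], ] - X[idx[2], ])^2))
    }))
    within / mean(apply(X, 2, sd))
  }
  raw_ns <- noise_to_signal(ds$spectra$absorbance)
  corr <- apply_pretreatment(ds$spectra$absorbance, method = "msc+1d")$cal
  expect_lt(noise_to_signal(corr), raw_ns)
})
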
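test_that("wavenumber grid is descending, evenly spaced, and validates bounds", {
  g <- make_wavenumber_grid(10000, 4000, 1557)
  spacing <- (10000 - 4000) / 1556
  expect_equal(g[1], 10000)
  expect_equal(g[1557], 4000)
  expect_equal(unique(round(-diff(g), 10)), round(spacing, 10))
  expect_equal(spacing, 3.8560, tolerance = 1e-4)
  # spacing * (n-1) + end recovers start to machine precision
  expect_equal(spacing * 1556 + 4000, 10000)
  expect_equal(make_wavenumber_grid(10, 0, 2), c(10, 0))
  expect_error(make_wavenumber_grid(4000, 10000, 100), "descending")
  expect_error(make_wavenumber_grid(10, 0, 1), "n_points")
})

test_that("pure_spectrum is a linear Gaussian band superposition", {
  g <- make_wavenumber_grid(10000, 4000, 1557)
  b <- nir_band(center = g[300], width = 50, amplitude = 1)
  s <- pure_spectrum(b, g)
  expect_equal(s[300], 1)
  expect_equal(which.max(s), 300L)
  expect_equal(pure_spectrum(rbind(b, b), g), 2 * s)
  expect_equal(pure_spectrum(b[0, ], g), numeric(1557))
  # quadrature vs closed-form Gaussian integral, 1% tolerance
  spacing <- (10000 - 4000) / 1556
  b2 <- nir_band(center = 7000, width = 100, amplitude = 0.7)
  s2 <- pure_spectrum(b2, g)
  expect_equal(sum(s2) * spacing, 0.7 * 100 * sqrt(2 * pi), tolerance = 0.01)
  expect_error(nir_band(5000, -1, 1), "width")
  expect_error(nir_band(5000, 10, -0.1), "amplitude")
})

test_that("generator is deterministic under a fixed seed", {
  a <- generate_nir_dataset(small_synth_config(seed = 42))
  b <- generate_nir_dataset(small_synth_config(seed = 42))
  expect_identical(a$spectra$absorbance, b$spectra$absorbance)
  expect_identical(a$reference, b$reference)
  c <- generate_nir_dataset(small_synth_config(seed = 43))
  expect_false(identical(a$spectra$absorbance, c$spectra$absorbance))
})

test_that("noiseless unit-gain spectra are exact Beer-Lambert mixtures", {
  cfg <- small_synth_config(seed = 7, noise_sd = 0, gain_range = c(1, 1),
                            baseline_scale = 0)
  ds <- generate_nir_dataset(cfg)
  wn <- ds$spectra$wavenumbers
  S <- cbind(pure_spectrum(cfg$analyte_bands$ferulic_acid, wn),
             pure_spectrum(cfg$analyte_bands$z_ligustilide, wn))
  # rank <= 2 analytes + 3 distinct class backgrounds
  d <- svd(ds$spectra$absorbance)$d
  expect_lte(sum(d > d[1] * 1e-8), 5)
  # OLS deconvolution recovers the stored truth
  bg <- lapply(names(cfg$n_per_class), function(cl) {
    b <- cfg$background_bands
    b$amplitude <- b$amplitude * cfg$class_background_scale[[cl]]
    pure_spectrum(b, wn)
  })
  names(bg) <- names(cfg$n_per_class)
  first_reps <- !duplicated(ds$spectra$replicate_group)
  X <- ds$spectra$absorbance[first_reps, , drop = FALSE]
  for (i in seq_len(nrow(X))) {
    cl <- ds$reference$origin[i]
    ch <- coef(lm(X[i, ] - bg[[cl]] ~ 0 + S))
    truth <- as.numeric(ds$reference[i, c("ferulic_acid", "z_ligustilide")])
    expect_equal(unname(ch), truth, tolerance = 1e-8)
  }
})

test_that("origin classes differ in mean concentration as configured", {
  cfg <- synth_config(n_per_class = c(Gansu = 80, Qinghai = 80),
                      n_points = 120, n_replicates = 1, seed = 3)
  ds <- generate_nir_dataset(cfg)
  for (a in c("ferulic_acid", "z_ligustilide")) {
    rg <- cfg$conc_ranges[[a]]$Gansu; rq <- cfg$conc_ranges[[a]]$Qinghai
    expected <- mean(rg) - mean(rq)
    vg <- ds$reference[[a]][ds$reference$origin == "Gansu"]
    vq <- ds$reference[[a]][ds$reference$origin == "Qinghai"]
    se <- sqrt(diff(rg)^2 / 12 / 80 + diff(rq)^2 / 12 / 80)
    expect_lt(abs((mean(vg) - mean(vq)) - expected), 3 * se)
  }
})

test_that("replicate averaging is the per-group arithmetic mean", {
  X <- rbind(c(0, 2), c(2, 4), c(5, 5), c(5, 5), c(5, 5))
  sp <- spectra_set(X, c(8000, 4000), sample_id = paste0("s", 1:5),
                    replicate_group = c("g1", "g1", "g2", "g2", "g2"))
  avg <- average_replicates(sp)
  expect_equal(nrow(avg$absorbance), 2L)
  expect_equal(unname(avg$absorbance["g1", ]), c(1, 3))
  expect_equal(unname(avg$absorbance["g2", ]), c(5, 5))
  expect_equal(avg$sample_id, c("g1", "g2"))
  expect_error(average_replicates(spectra_set(X, c(8000, 4000))), "grouping")
  ds <- small_dataset()
  avg2 <- average_replicates(ds$spectra)
  expect_equal(nrow(avg2$absorbance), length(unique(ds$spectra$replicate_group)))
  expect_identical(avg2$sample_id, ds$reference$sample_id)
})
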
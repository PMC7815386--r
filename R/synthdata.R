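#' Evenly spaced descending wavenumber grid
#'
#' FT-NIR spectra are conventionally stored from high to low wavenumber, so
#' `start` must exceed `end`. The default workflow grid spans
#' 10,000-4,000 cm-1 in 1557 points (spacing ~3.8560 cm-1), the point
#' density of a diffuse-reflectance FT-NIR instrument at 8 cm-1 resolution.
#'
#' @param start first (highest) wavenumber, cm-1.
#' @param end last (lowest) wavenumber, cm-1.
#' @param n_points number of grid points (>= 2).
#' @return strictly decreasing numeric vector of length `n_points`.
#' @export
make_wavenumber_grid <- function(start = 10000, end = 4000, n_points = 1557) {
  if (!(start > end))
    stop_invalid("grid bounds must be descending (start > end); got %g, %g",
                 start, end)
  if (n_points < 2) stop_invalid("n_points must be >= 2")
  seq(start, end, length.out = n_points)
}

#' Gaussian absorption band
#'
#' @param center band centre in cm-1.
#' @param width Gaussian sigma in cm-1 (> 0).
#' @param amplitude peak absorbance; for analyte bands this is absorbance per
#'   (mg/g), for background bands an absolute absorbance.
#' @return one-row `data.frame` with columns `center`, `width`, `amplitude`;
#'   `rbind` several to form a band list.
#' @export
nir_band <- function(center, width, amplitude) {
  if (any(width <= 0)) stop_invalid("band width must be > 0")
  if (any(amplitude < 0)) stop_invalid("band amplitude must be >= 0")
  data.frame(center = center, width = width, amplitude = amplitude)
}

#' Evaluate a sum of Gaussian bands on a wavenumber grid
#'
#' @param bands `data.frame` of bands from [nir_band()]; zero rows give the
#'   zero spectrum.
#' @param wavenumbers numeric wavenumber grid.
#' @return numeric vector, the pure-component spectrum.
#' @export
pure_spectrum <- function(bands, wavenumbers) {
  s <- numeric(length(wavenumbers))
  if (is.null(bands) || nrow(bands) == 0) return(s)
  for (i in seq_len(nrow(bands))) {
    s <- s + bands$amplitude[i] *
      exp(-(wavenumbers - bands$center[i])^2 / (2 * bands$width[i]^2))
  }
  s
}

#' Default band lists for the synthetic ASR-like dataset
#'
#' The background bands sit at the common absorption positions of powdered
#' Angelicae Sinensis Radix spectra (C-H second overtone near 8350 cm-1,
#' O-H/N-H first overtones at 6000-7000 cm-1, C-H first overtones at
#' 5500-6000 cm-1, O-H/C-O combination bands near 4813 and 4313 cm-1). The
#' analyte bands place the ferulic-acid-like component inside
#' 5488-5191 and 4590-4297 cm-1 and the Z-ligustilide-like component inside
#' 5488-5191, 4590-4297 and 4293-4000 cm-1, so interval-selection methods
#' have a known ground truth. Amplitudes are free parameters of the
#' simulation (per-band intensities of the real material are not published);
#' they are scaled so each analyte contributes ~0.1-0.2 absorbance at the
#' top of its concentration range.
#'
#' @return a `data.frame` of bands ([nir_band()] rows).
#' @export
default_background_bands <- function() {
  nir_band(center = c(8350, 6961, 6736, 6323, 5917, 5788, 5712, 4813, 4313),
           width = c(180, 120, 110, 130, 100, 90, 90, 120, 110),
           amplitude = c(0.15, 0.35, 0.30, 0.25, 0.45, 0.40, 0.35, 0.55, 0.50))
}

#' @rdname default_background_bands
#' @export
default_analyte_bands <- function() {
  list(
    ferulic_acid = nir_band(center = c(5340, 4440),
                            width = c(60, 50),
                            amplitude = c(0.050, 0.035)),
    z_ligustilide = nir_band(center = c(5250, 4520, 4150),
                             width = c(55, 45, 60),
                             amplitude = c(0.0085, 0.0065, 0.0075))
  )
}

# Per-class multiplicative modulation of the background band amplitudes:
# origin classes share band positions but differ a few percent in relative
# band intensity, mimicking compositional differences between provenances.
default_class_background_scale <- function() {
  list(
    Gansu   = rep(1, 9),
    Yunnan  = c(1.00, 1.06, 1.00, 0.96, 1.00, 1.05, 1.00, 0.94, 1.00),
    Qinghai = c(1.00, 0.93, 1.05, 1.00, 1.06, 1.00, 0.95, 1.00, 1.04)
  )
}

#' Configuration of the synthetic NIR dataset generator
#'
#' Defaults emulate the study design the package targets: 99 samples from
#' three origin classes (Gansu 54, Yunnan 25, Qinghai 20), each scanned in
#' triplicate on a 1557-point 10,000-4,000 cm-1 grid, with ferulic acid
#' spanning 0.4730-2.7307 mg/g and Z-ligustilide 2.2710-19.6627 mg/g over
#' the whole set. Classes differ in mean analyte concentration (per-class
#' uniform ranges) and in background band intensities. Each replicate scan
#' gets its own multiplicative scatter gain (Uniform 0.9-1.1), linear
#' additive baseline, and white noise.
#'
#' @param n_per_class named integer vector of samples per origin class.
#' @param grid_start,grid_end,n_points wavenumber grid, see
#'   [make_wavenumber_grid()].
#' @param conc_ranges per-analyte, per-class concentration ranges (mg/g).
#' @param analyte_bands named list of band `data.frame`s, one per analyte.
#' @param background_bands band `data.frame` for the shared matrix background.
#' @param class_background_scale named list of per-band multipliers per class.
#' @param gain_range multiplicative scatter gain range (dimensionless).
#' @param baseline_degree,baseline_scale additive baseline polynomial degree
#'   and coefficient scale (absorbance units).
#' @param noise_sd white-noise standard deviation (absorbance units).
#' @param n_replicates replicate scans per sample.
#' @param seed integer RNG seed; the same seed gives byte-identical datasets.
#' @return validated config list of class `synth_config`.
#' @export
synth_config <- function(
    n_per_class = c(Gansu = 54, Yunnan = 25, Qinghai = 20),
    grid_start = 10000, grid_end = 4000, n_points = 1557,
    conc_ranges = list(
      ferulic_acid = list(Gansu = c(0.90, 2.7307),
                          Yunnan = c(0.60, 1.80),
                          Qinghai = c(0.4730, 1.30)),
      z_ligustilide = list(Gansu = c(8.00, 19.6627),
                           Yunnan = c(5.00, 14.00),
                           Qinghai = c(2.2710, 10.00))),
    analyte_bands = default_analyte_bands(),
    background_bands = default_background_bands(),
    class_background_scale = default_class_background_scale(),
    gain_range = c(0.9, 1.1),
    baseline_degree = 1, baseline_scale = 0.03,
    noise_sd = 0.002,
    n_replicates = 3,
    seed = 20210112) {
  classes <- names(n_per_class)
  if (is.null(classes) || any(classes == ""))
    stop_invalid("n_per_class must be a named vector of class sizes")
  if (any(n_per_class < 1)) stop_invalid("each class needs >= 1 sample")
  for (a in names(conc_ranges)) for (cl in classes) {
    r <- conc_ranges[[a]][[cl]]
    if (is.null(r) || length(r) != 2 || !(r[1] < r[2]))
      stop_invalid("conc_ranges$%s$%s must be c(low, high) with low < high", a, cl)
    if (r[1] < 0) stop_invalid("concentrations must be >= 0 (%s, %s)", a, cl)
  }
  if (!setequal(names(analyte_bands), names(conc_ranges)))
    stop_invalid("analyte_bands and conc_ranges must name the same analytes")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (n_replicates < 1) stop_invalid("n_replicates must be >= 1")
  if (!(gain_range[1] <= gain_range[2]) || gain_range[1] <= 0)
    stop_invalid("gain_range must be positive and non-decreasing")
  structure(list(
    n_per_class = n_per_class, grid_start = grid_start, grid_end = grid_end,
    n_points = n_points, conc_ranges = conc_ranges,
    analyte_bands = analyte_bands, background_bands = background_bands,
    class_background_scale = class_background_scale,
    gain_range = gain_range, baseline_degree = baseline_degree,
    baseline_scale = baseline_scale, noise_sd = noise_sd,
    n_replicates = n_replicates, seed = seed), class = "synth_config")
}

#' Generate a synthetic NIR dataset with known ground truth
#'
#' Each replicate spectrum is built by Beer-Lambert linear mixing,
#' `gain * (c_1 * S_1 + c_2 * S_2 + background_class) + baseline + noise`,
#' where the `S_a` are unit-concentration analyte spectra, `background_class`
#' is the class-specific matrix background, `gain` is a per-replicate
#' multiplicative scatter factor, and `baseline` a per-replicate low-order
#' polynomial in the (scaled) wavenumber axis.
#'
#' @param config a [synth_config()].
#' @return a list with `spectra` (a [spectra_set()] of all replicate scans,
#'   with `replicate_group` naming the physical sample) and `reference`
#'   (one-row-per-sample `data.frame`: `sample_id`, `origin`, true analyte
#'   concentrations in mg/g).
#' @export
generate_nir_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  wn <- make_wavenumber_grid(config$grid_start, config$grid_end, config$n_points)
  p <- length(wn)
  analytes <- names(config$analyte_bands)
  S <- vapply(config$analyte_bands, pure_spectrum, numeric(p), wavenumbers = wn)
  t01 <- seq(0, 1, length.out = p)  # baseline axis, 0 at high wavenumber
  classes <- names(config$n_per_class)
  bg_class <- lapply(classes, function(cl) {
    b <- config$background_bands
    scl <- config$class_background_scale[[cl]]
    if (is.null(scl)) scl <- rep(1, nrow(b))
    b$amplitude <- b$amplitude * scl
    pure_spectrum(b, wn)
  })
  names(bg_class) <- classes

  with_seed(config$seed, {
    rows <- list(); ids <- character(); groups <- character(); origins <- character()
    ref_id <- character(); ref_origin <- character()
    conc <- matrix(0, 0, length(analytes), dimnames = list(NULL, analytes))
    for (cl in classes) {
      for (i in seq_len(config$n_per_class[[cl]])) {
        gid <- sprintf("%s_%02d", cl, i)
        ci <- vapply(analytes, function(a) {
          r <- config$conc_ranges[[a]][[cl]]
          runif(1, r[1], r[2])
        }, numeric(1))
        truth <- drop(S %*% ci) + bg_class[[cl]]
        for (r in seq_len(config$n_replicates)) {
          gain <- runif(1, config$gain_range[1], config$gain_range[2])
          base <- numeric(p)
          for (d in 0:config$baseline_degree)
            base <- base + runif(1, -config$baseline_scale, config$baseline_scale) * t01^d
          eps <- if (config$noise_sd > 0) rnorm(p, 0, config$noise_sd) else numeric(p)
          rows[[length(rows) + 1L]] <- gain * truth + base + eps
          ids <- c(ids, sprintf("%s_r%d", gid, r))
          groups <- c(groups, gid)
          origins <- c(origins, cl)
        }
        ref_id <- c(ref_id, gid); ref_origin <- c(ref_origin, cl)
        conc <- rbind(conc, ci)
      }
    }
    X <- do.call(rbind, rows)
    reference <- data.frame(sample_id = ref_id, origin = ref_origin,
                            stringsAsFactors = FALSE)
    for (a in analytes) reference[[a]] <- conc[, a]
    list(spectra = spectra_set(X, wn, sample_id = ids, origin = origins,
                               replicate_group = groups),
         reference = reference)
  })
}

#' Average replicate scans
#'
#' Collapses a spectra set to one arithmetic-mean spectrum per replicate
#' group, the usual treatment of triplicate NIR scans before modelling.
#'
#' @param spectra a [spectra_set()].
#' @param groups grouping vector (defaults to `spectra$replicate_group`).
#' @return a [spectra_set()] with one row per group, in first-appearance
#'   order; `sample_id` becomes the group id.
#' @export
average_replicates <- function(spectra, groups = spectra$replicate_group) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (is.null(groups))
    stop_invalid("no replicate grouping available")
  groups <- as.character(groups)
  if (length(groups) != nrow(spectra$absorbance))
    stop_invalid("groups length != number of spectra")
  uniq <- unique(groups)
  counts <- table(groups)
  if (any(counts == 0) || length(uniq) == 0)
    stop_invalid("every replicate group must contain at least one spectrum")
  X <- rowsum(spectra$absorbance, group = groups, reorder = FALSE)
  X <- X / as.vector(counts[rownames(X)])
  origin <- NULL
  if (!is.null(spectra$origin)) {
    origin <- vapply(uniq, function(g) {
      o <- unique(spectra$origin[groups == g])
      if (length(o) != 1)
        stop_invalid("replicate group '%s' has inconsistent origin labels", g)
      o
    }, character(1))
  }
  spectra_set(X[uniq, , drop = FALSE], spectra$wavenumbers,
              sample_id = uniq, origin = origin)
}
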
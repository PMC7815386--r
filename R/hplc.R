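#' External-standard HPLC calibration curve
#'
#' Ordinary least squares of peak area on standard concentration,
#' `area = slope * conc + intercept`, with the squared Pearson correlation
#' as r2 and the fitted concentration range recorded for extrapolation
#' checks.
#'
#' @param concentration standard concentrations, ug/mL (>= 2 distinct).
#' @param area corresponding peak areas.
#' @return list of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `range` (ug/mL).
#' @export
fit_calibration_curve <- function(concentration, area) {
  if (length(unique(concentration)) < 2)
    stop_invalid("need >= 2 distinct concentrations")
  if (length(concentration) != length(area))
    stop_invalid("concentration and area differ in length")
  fit <- lm(area ~ concentration)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = cor(concentration, area)^2,
                 range = range(concentration)),
            class = "calibration_curve")
}

#' Evaluate a calibration curve (area expected at a concentration)
#'
#' @param curve a `calibration_curve`.
#' @param concentration ug/mL.
#' @return predicted peak area.
#' @export
curve_response <- function(curve, concentration) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$slope * concentration + curve$intercept
}

#' Quantify an analyte from a peak area
#'
#' Inverts the calibration curve and converts the solution concentration to
#' content per dry mass: `mg/g = conc(ug/mL) * volume(mL) * dilution /
#' (mass(g) * 1000)`. The defaults (0.2 g extracted in 20 mL) are the usual
#' reflux-extraction scale. An area whose inverted concentration falls
#' outside the fitted range is returned with attribute
#' `extrapolated = TRUE` and a warning.
#'
#' @param curve a `calibration_curve`.
#' @param area measured peak area.
#' @param dilution dilution factor (default 1).
#' @param sample_mass_g sample dry mass, g.
#' @param extract_volume_ml extraction volume, mL.
#' @return content in mg/g (with attribute `extrapolated`).
#' @export
quantify_content <- function(curve, area, dilution = 1,
                             sample_mass_g = 0.2, extract_volume_ml = 20) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (sample_mass_g <= 0 || extract_volume_ml <= 0 || dilution <= 0)
    stop_invalid("mass, volume and dilution must be > 0")
  conc <- (area - curve$intercept) / curve$slope
  outside <- conc < curve$range[1] | conc > curve$range[2]
  if (any(outside))
    warning("inverted concentration outside the fitted calibration range",
            call. = FALSE)
  out <- conc * extract_volume_ml * dilution / (sample_mass_g * 1000)
  attr(out, "extrapolated") <- outside
  out
}

#' Relative standard deviation
#'
#' @param values numeric vector, n >= 2, nonzero mean.
#' @return `100 * sd / mean`, percent.
#' @export
rsd <- function(values) {
  if (length(values) < 2) stop_invalid("RSD needs >= 2 values")
  m <- mean(values)
  if (m == 0) stop_invalid("RSD undefined for zero mean")
  100 * sd(values) / m
}

#' Spike recovery
#'
#' @param found total amount measured in the spiked sample.
#' @param base amount in the unspiked sample.
#' @param added amount spiked in (> 0).
#' @return recovery percent, `100 * (found - base) / added`.
#' @export
recovery <- function(found, base, added) {
  if (any(added <= 0)) stop_invalid("added amount must be > 0")
  100 * (found - base) / added
}
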
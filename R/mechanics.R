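#' Construct a tensile record
#'
#' Container for a uniaxial tensile test: time, crosshead displacement and
#' load, plus the initial strip geometry needed to reduce the record to
#' engineering stress and strain.
#'
#' @param time_s,displacement_mm,load_N Equal-length numeric columns
#'   (>= 3 points); time must be strictly increasing.
#' @param strip_width_mm,thickness_mm,gauge_length_mm Strip geometry, mm,
#'   all strictly positive.
#' @return An object of class `tensile_record` (a data frame with geometry
#'   attributes).
#' @export
tensile_record <- function(time_s, displacement_mm, load_N,
                           strip_width_mm, thickness_mm, gauge_length_mm) {
  n <- length(time_s)
  if (n < 3 || length(displacement_mm) != n || length(load_N) != n)
    stop("columns must have equal length >= 3", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("`time_s` must be strictly increasing", call. = FALSE)
  for (nm in c("strip_width_mm", "thickness_mm", "gauge_length_mm"))
    stop_if_not_scalar_pos(get(nm), nm)
  out <- data.frame(time_s = time_s, displacement_mm = displacement_mm,
                    load_N = load_N)
  attr(out, "strip_width_mm") <- strip_width_mm
  attr(out, "thickness_mm") <- thickness_mm
  attr(out, "gauge_length_mm") <- gauge_length_mm
  class(out) <- c("tensile_record", "data.frame")
  out
}

#' Reduce a tensile record to engineering stress and strain
#'
#' Engineering stress is load over the initial cross-section
#' (`N / mm^2 = MPa`); engineering strain is displacement change from the
#' first sample over the gauge length. No cross-section updating is applied.
#'
#' @param record A [tensile_record()].
#' @return An object of class `stress_strain_curve`: data frame with columns
#'   `strain` (dimensionless, starts at 0) and `stress_MPa`.
#' @export
compute_stress_strain <- function(record) {
  stopifnot(inherits(record, "tensile_record"))
  area_mm2 <- attr(record, "strip_width_mm") * attr(record, "thickness_mm")
  out <- data.frame(
    strain = (record$displacement_mm - record$displacement_mm[1]) /
      attr(record, "gauge_length_mm"),
    stress_MPa = record$load_N / area_mm2)
  class(out) <- c("stress_strain_curve", "data.frame")
  out
}

#' Estimate Young's modulus from a stress-strain curve
#'
#' Ordinary least-squares slope of stress against strain restricted to the
#' window `[fit_lo_frac, fit_hi_frac] * max(strain)`. For J-shaped soft
#' tissue curves the default window \[0.7, 0.9\] targets the upper, nearly
#' linear regime where collagen fibrils are recruited; for a perfectly
#' linear curve any window returns the same slope.
#'
#' @param curve A [compute_stress_strain()] result.
#' @param fit_lo_frac,fit_hi_frac Fractions of the maximum strain bounding
#'   the fit window, `0 <= lo < hi <= 1`.
#' @return An object of class `modulus_estimate`: list with
#'   `young_modulus_MPa`, `fit_strain_lo`, `fit_strain_hi`, `r_squared`,
#'   `n_points`.
#' @export
estimate_modulus <- function(curve, fit_lo_frac = 0.7, fit_hi_frac = 0.9) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (fit_lo_frac < 0 || fit_hi_frac > 1 || fit_lo_frac >= fit_hi_frac)
    stop("need 0 <= fit_lo_frac < fit_hi_frac <= 1", call. = FALSE)
  smax <- max(curve$strain)
  lo <- fit_lo_frac * smax; hi <- fit_hi_frac * smax
  sel <- curve$strain >= lo & curve$strain <= hi
  if (sum(sel) < 2)
    stop(sprintf("fit window [%g, %g] contains %d point(s); need >= 2",
                 lo, hi, sum(sel)), call. = FALSE)
  fit <- lm(stress_MPa ~ strain, data = curve[sel, , drop = FALSE])
  y <- curve$stress_MPa[sel]
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  structure(list(young_modulus_MPa = unname(coef(fit)[2]),
                 fit_strain_lo = lo, fit_strain_hi = hi,
                 r_squared = min(max(r2, 0), 1), n_points = sum(sel)),
            class = "modulus_estimate")
}

#' @export
print.modulus_estimate <- function(x, ...) {
  cat(sprintf(
    "<modulus_estimate> E = %.3f MPa (strain window [%.3g, %.3g], n = %d, R^2 = %.4f)\n",
    x$young_modulus_MPa, x$fit_strain_lo, x$fit_strain_hi, x$n_points,
    x$r_squared))
  invisible(x)
}
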
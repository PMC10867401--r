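#' Parallel-plate capacitance
#'
#' Forward model of the capacitive pressure sensor: `C = eps * A / d`.
#' Units are whatever consistent system the caller uses; with relative
#' permittivity, area in m^2 and thickness in m the result is in units of
#' vacuum-permittivity x metre.
#'
#' @param permittivity (relative) permittivity of the dielectric layer.
#' @param area plate contact area.
#' @param thickness dielectric layer thickness; must be non-zero.
#' @return Capacitance, `permittivity * area / thickness`. Vectorized.
#' @examples
#' capacitance(2, 3, 1.5)  # 4
#' @export
capacitance <- function(permittivity, area, thickness) {
  if (any(thickness == 0)) stop("dielectric thickness must be non-zero")
  if (any(permittivity <= 0) || any(area <= 0) || any(thickness < 0))
    stop("capacitor geometry parameters must be strictly positive")
  permittivity * area / thickness
}

#' Permittivity of a porous two-phase dielectric
#'
#' Volume-weighted mixture rule for a porous composite dielectric: the
#' effective permittivity is `eps_air * vol_air + eps_composite *
#' vol_composite`. Compression collapses pores (shrinking `vol_air`), which
#' raises the effective permittivity - the mechanism behind the sensor's
#' pressure response.
#'
#' @param vol_air air (pore) volume fraction in `[0, 1]`.
#' @param eps_composite relative permittivity of the solid composite phase.
#' @param vol_composite solid volume fraction; defaults to `1 - vol_air` and
#'   must sum to 1 with `vol_air` (tolerance 1e-9).
#' @param eps_air relative permittivity of air (1).
#' @return Effective relative permittivity. Vectorized over fractions.
#' @examples
#' mixture_permittivity(0.5, eps_composite = 5)  # 3
#' @export
mixture_permittivity <- function(vol_air, eps_composite,
                                 vol_composite = 1 - vol_air, eps_air = 1) {
  if (any(vol_air < 0 | vol_air > 1) || any(vol_composite < 0 | vol_composite > 1))
    stop("volume fractions must lie in [0, 1]")
  if (any(abs(vol_air + vol_composite - 1) > 1e-9))
    stop("volume fractions must sum to 1")
  eps_air * vol_air + eps_composite * vol_composite
}

#' Piecewise-linear pressure/capacitance calibration curve
#'
#' The sensor's relative capacitance change (dC/C0) versus pressure response
#' is modelled as two exact linear segments: sensitivity `sensitivity_low`
#' below the `breakpoint` and `sensitivity_high` above it, continuous at the
#' breakpoint. Defaults are the bench-characterized values: 0.0126 kPa^-1 on
#' 0-200 kPa and 0.0038 kPa^-1 on 200-500 kPa, with a 0.4 kPa detection
#' limit.
#'
#' @param sensitivity_low sensitivity below the breakpoint, kPa^-1.
#' @param sensitivity_high sensitivity above the breakpoint, kPa^-1.
#' @param breakpoint segment boundary, kPa.
#' @param detection_limit smallest resolvable pressure, kPa; inverse-mapped
#'   readings below it are censored to 0.
#' @param max_pressure upper end of the validated range, kPa.
#' @param baseline_capacitance unloaded capacitance C0, pF (bookkeeping only;
#'   the curve works in relative units).
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(sensitivity_low = 0.0126, sensitivity_high = 0.0038,
                              breakpoint = 200, detection_limit = 0.4,
                              max_pressure = 500, baseline_capacitance = 1) {
  if (!(sensitivity_low > sensitivity_high && sensitivity_high > 0))
    stop("require sensitivity_low > sensitivity_high > 0")
  if (!(detection_limit > 0 && detection_limit < breakpoint &&
        breakpoint < max_pressure))
    stop("require 0 < detection_limit < breakpoint < max_pressure")
  if (baseline_capacitance <= 0) stop("baseline_capacitance must be positive")
  structure(
    list(sensitivity_low = sensitivity_low, sensitivity_high = sensitivity_high,
         breakpoint = breakpoint, detection_limit = detection_limit,
         max_pressure = max_pressure, baseline_capacitance = baseline_capacitance),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> S = %.4g kPa^-1 on [0, %g] kPa, %.4g kPa^-1 on (%g, %g] kPa\n",
              x$sensitivity_low, x$breakpoint, x$sensitivity_high,
              x$breakpoint, x$max_pressure))
  cat(sprintf("  detection limit %g kPa, C0 = %g pF\n",
              x$detection_limit, x$baseline_capacitance))
  invisible(x)
}

#' Convert pressure to relative capacitance change
#'
#' @param p pressure in kPa, within `[0, max_pressure]`.
#' @param curve a [calibration_curve()].
#' @return Relative capacitance change dC/C0 (dimensionless). Vectorized.
#' @examples
#' curve <- calibration_curve()
#' pressure_to_relcap(100, curve)  # 1.26
#' @export
pressure_to_relcap <- function(p, curve = calibration_curve()) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(p < 0) || any(p > curve$max_pressure))
    stop("pressure outside the validated range [0, ", curve$max_pressure, "] kPa")
  ifelse(p <= curve$breakpoint,
         curve$sensitivity_low * p,
         curve$sensitivity_low * curve$breakpoint +
           curve$sensitivity_high * (p - curve$breakpoint))
}

#' Convert relative capacitance change to pressure
#'
#' Exact inverse of [pressure_to_relcap()]; pressures that invert below the
#' detection limit are reported as 0 (censored).
#'
#' @param relcap relative capacitance change dC/C0, non-negative and at most
#'   `pressure_to_relcap(max_pressure)`.
#' @param curve a [calibration_curve()].
#' @return Pressure in kPa. Vectorized.
#' @examples
#' relcap_to_pressure(1.26, calibration_curve())  # 100
#' @export
relcap_to_pressure <- function(relcap, curve = calibration_curve()) {
  stopifnot(inherits(curve, "calibration_curve"))
  rc_max <- pressure_to_relcap(curve$max_pressure, curve)
  if (any(relcap < 0)) stop("relative capacitance change must be non-negative")
  if (any(relcap > rc_max + 1e-9))
    stop("relative capacitance change above the calibrated range (max ",
         signif(rc_max, 6), ")")
  rc_break <- curve$sensitivity_low * curve$breakpoint
  p <- ifelse(relcap <= rc_break,
              relcap / curve$sensitivity_low,
              curve$breakpoint + (relcap - rc_break) / curve$sensitivity_high)
  ifelse(p < curve$detection_limit, 0, p)
}

#' Calibrate a raw capacitance series to pressure
#'
#' Applies [relcap_to_pressure()] channel-wise to a series recorded in
#' relative capacitance units.
#'
#' @param series a [pressure_series()] with `unit = "relcap"`.
#' @param curve a [calibration_curve()] (one curve shared by all channels),
#'   or a named list of per-channel curves (`S1`..`S8`).
#' @return A [pressure_series()] in kPa.
#' @export
calibrate_series <- function(series, curve = calibration_curve()) {
  stopifnot(inherits(series, "pressure_series"))
  if (series$unit != "relcap")
    stop("series is already calibrated (unit ", series$unit, ")")
  vals <- series$values
  if (inherits(curve, "calibration_curve")) {
    vals[] <- relcap_to_pressure(as.vector(vals), curve)
  } else {
    stopifnot(is.list(curve), all(paste0("S", 1:8) %in% names(curve)))
    for (ch in paste0("S", 1:8))
      vals[, ch] <- relcap_to_pressure(vals[, ch], curve[[ch]])
  }
  pressure_series(vals, sample_rate = series$sample_rate,
                  annotation = series$annotation, unit = "kPa")
}
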
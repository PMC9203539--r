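# One-time device calibration from hard-backed cavity sessions: a cubic
# least-squares fit of (amplitude at +200 daPa, known volume) pairs maps raw
# probe-tone amplitude to mL, and a line fitted to the calibrated 0 mL cavity
# curve compensates the slow amplitude drift across the sweep.

#' Fit the cubic amplitude-to-volume map
#'
#' Ordinary least squares of volume on amplitude with a cubic polynomial.
#'
#' @param points Data frame with columns `amplitude` (uncalibrated magnitude
#'   at +200 daPa) and `volume` (mL, within \[0, 5\]); at least 4 distinct
#'   amplitudes.
#' @return Named numeric vector `c(p1, p2, p3, p4)` (cubic term first), with
#'   the fitted residuals in attribute `residuals`.
#' @examples
#' pts <- data.frame(amplitude = 0:5, volume = 0:5)
#' fit_cubic(pts) # identity map: c(0, 0, 1, 0)
#' @export
fit_cubic <- function(points) {
  if (!all(c("amplitude", "volume") %in% names(points)))
    validation_error("points needs columns amplitude and volume")
  x <- points$amplitude; v <- points$volume
  if (length(unique(x)) < 4L)
    fit_error("cubic fit needs at least 4 distinct amplitude values")
  if (any(v < 0 | v > 5))
    domain_error("calibration volumes must lie within [0, 5] mL")
  X <- cbind(x^3, x^2, x, 1)
  fit <- stats::lm.fit(X, v)
  if (fit$rank < 4L) fit_error("degenerate design: cubic fit is rank-deficient")
  co <- unname(fit$coefficients)
  structure(c(p1 = co[1], p2 = co[2], p3 = co[3], p4 = co[4]),
            residuals = unname(fit$residuals))
}

#' Fit the slope-compensation line to the 0 mL cavity curve
#'
#' Least-squares slope `m` of the calibrated 0 mL tympanogram over the full
#' -400..+200 daPa span, and `b`, the fitted line's value at -400 daPa. The
#' compensation subtracted at pressure p is `m * (p + 400) + b`.
#'
#' @param zero_ml_curve A [tympanogram()] (or data frame with
#'   `pressure_daPa`, `admittance_mL`) spanning the full grid.
#' @return Named numeric vector `c(m, b)`.
#' @export
fit_slope <- function(zero_ml_curve) {
  if (!all(c("pressure_daPa", "admittance_mL") %in% names(zero_ml_curve)))
    validation_error("curve needs columns pressure_daPa and admittance_mL")
  p <- zero_ml_curve$pressure_daPa; y <- zero_ml_curve$admittance_mL
  if (min(p) > -397.5 || max(p) < 197.5)
    domain_error("the 0 mL curve must span the full -400..+200 daPa range")
  m <- ls_slope(p, y)
  b <- mean(y) + m * (-400 - mean(p))
  c(m = m, b = b)
}

#' Calibrate a device from the six cavity sessions
#'
#' Runs each cavity session through [synchronize()] and
#' [extract_raw_curve()], takes the amplitude at the +200 daPa end of the
#' sweep (mean over samples at 170 daPa and above, which averages out
#' segment-level leakage ripple), fits the cubic with [fit_cubic()], then
#' normalizes the 0 mL curve with the cubic, smooths it, and fits the
#' compensation line with [fit_slope()].
#'
#' @param sessions List of [tymp_session()]s, one per cavity volume.
#' @param volumes Cavity volumes in mL matching `sessions` (default `0:5`);
#'   all of 0..5 must be present.
#' @param gain_setting Speaker gain recorded in the model (default 85).
#' @return A [calibration_model()] with diagnostic attribute
#'   `cubic_rmse` (RMSE of the cubic at the cavity nodes, mL).
#' @export
calibrate_device <- function(sessions, volumes = 0:5, gain_setting = 85) {
  if (length(sessions) != length(volumes))
    validation_error("sessions and volumes must have equal length")
  missing <- setdiff(0:5, volumes)
  if (length(missing))
    calibration_error(paste0("calibration incomplete; missing cavity volume(s): ",
                             paste(missing, "mL", collapse = ", ")))
  curves <- purrr::map(sessions, function(s) {
    synced <- synchronize(s$audio, s$pressure, s$events)
    extract_raw_curve(synced, s$audio)
  })
  amp200 <- purrr::map_dbl(curves, function(cu) {
    top <- cu$amplitude[cu$pressure_daPa >= 170]
    if (!length(top)) top <- cu$amplitude[which.max(cu$pressure_daPa)]
    mean(top)
  })
  co <- fit_cubic(tibble::tibble(amplitude = amp200, volume = volumes))

  cal0 <- calibration_model(co[["p1"]], co[["p2"]], co[["p3"]], co[["p4"]],
                            m = 0, b = 0, gain_setting = gain_setting)
  zero_curve <- curves[[which(volumes == 0)[1]]]
  # the 0 mL curve is allowed below -0.1 mL here: the compensation line that
  # fixes exactly that is being fitted from it
  zero_cal <- withCallingHandlers(
    apply_calibration(zero_curve, cal0),
    tymp_calibration_warning = function(w) invokeRestart("muffleWarning"))
  zero_sm <- smooth_tympanogram(zero_cal, calibrated = FALSE)
  sl <- fit_slope(zero_sm)

  cal <- calibration_model(co[["p1"]], co[["p2"]], co[["p3"]], co[["p4"]],
                           m = sl[["m"]], b = sl[["b"]],
                           gain_setting = gain_setting,
                           amplitude_range = range(amp200))
  attr(cal, "cubic_rmse") <- sqrt(mean(attr(co, "residuals")^2))
  cal
}

#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(term = c("p1", "p2", "p3", "p4", "m", "b"),
                 estimate = c(x$p1, x$p2, x$p3, x$p4, x$m, x$b))
}

#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(cubic_rmse = attr(x, "cubic_rmse") %||% NA_real_,
                 monotone = isTRUE(calibration_is_monotone(x)),
                 gain_setting = x$gain_setting)
}

#' Predict calibrated volume from raw amplitude
#'
#' @param object A [calibration_model()].
#' @param amplitude Raw probe-tone bin magnitudes.
#' @param pressure_daPa Optional pressures; when given, the slope
#'   compensation line is subtracted.
#' @param ... Unused.
#' @return Calibrated mL values.
#' @export
predict.calibration_model <- function(object, amplitude, pressure_daPa = NULL,
                                      ...) {
  y <- calibration_map(object, amplitude)
  if (!is.null(pressure_daPa))
    y <- y - calibration_comp_line(object, pressure_daPa)
  y
}
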
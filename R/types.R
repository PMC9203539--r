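#' Construct an audio trace
#'
#' A mono audio recording carrying the reflected 226 Hz probe tone, stored in
#' normalized full-scale units (a full-scale sinusoid has amplitude 1). The
#' absolute sound level exists only through `level_reference`: the dB SPL that
#' a full-scale sinusoid corresponds to at the probe microphone. The default of
#' 85 dB SPL matches a probe driven at the standard tympanometric output level.
#'
#' @param samples Numeric vector of audio samples in \[-1, 1\] full-scale units.
#' @param sample_rate Sampling rate in Hz (default 24000).
#' @param level_reference dB SPL of a full-scale sinusoid (default 85).
#' @return An object of class `audio_trace`: a list with elements `samples`,
#'   `sample_rate`, `level_reference`.
#' @examples
#' a <- audio_trace(sin(2 * pi * 226 * seq(0, 1, by = 1 / 24000)))
#' a$sample_rate
#' @export
audio_trace <- function(samples, sample_rate = 24000, level_reference = 85) {
  if (!is.numeric(samples) || length(samples) < 1L)
    validation_error("audio samples must be numeric with length >= 1")
  if (anyNA(samples) || any(!is.finite(samples)))
    validation_error("audio samples must be finite")
  if (!is_number(sample_rate) || sample_rate <= 0)
    validation_error("sample_rate must be a positive number")
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         level_reference = as.numeric(level_reference)),
    class = "audio_trace")
}

#' @export
print.audio_trace <- function(x, ...) {
  cat(sprintf("<audio_trace> %d samples @ %g Hz (%.2f s), full scale = %g dB SPL\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$level_reference))
  invisible(x)
}

#' Construct a pressure trace
#'
#' Timestamped air-pressure samples in daPa relative to ambient (gauge), as
#' produced by the in-line pressure sensor or the simulator. Times must be
#' strictly increasing; pressures are sanity-bounded to \[-1000, 1000\] daPa.
#'
#' @param data Data frame with numeric columns `time_s` and `pressure_daPa`.
#' @return A tibble of class `pressure_trace` with columns `time_s`,
#'   `pressure_daPa`.
#' @examples
#' pressure_trace(data.frame(time_s = 0:9 / 10, pressure_daPa = rep(0, 10)))
#' @export
pressure_trace <- function(data) {
  if (!is.data.frame(data) || !all(c("time_s", "pressure_daPa") %in% names(data)))
    validation_error("pressure data needs columns time_s and pressure_daPa")
  t <- data$time_s; p <- data$pressure_daPa
  if (length(t) != length(p))
    validation_error("time_s and pressure_daPa must have equal length")
  if (anyNA(t) || anyNA(p) || any(!is.finite(t)) || any(!is.finite(p)))
    validation_error("pressure trace values must be finite")
  if (length(t) > 1L && any(diff(t) <= 0))
    validation_error("time_s must be strictly increasing")
  if (any(p < -1000 | p > 1000))
    validation_error("pressure_daPa outside the sane range [-1000, 1000]")
  out <- tibble::tibble(time_s = as.numeric(t), pressure_daPa = as.numeric(p))
  class(out) <- c("pressure_trace", class(out))
  out
}

#' Construct session events
#'
#' Event timestamps on the audio clock: when a seal was found or lost, and the
#' (jitter-delayed) notifications marking the beginning and end of the
#' pressure sweep. `NA` marks an absent event.
#'
#' @param seal_found_t,sweep_start_notify_t,sweep_end_notify_t,seal_lost_t
#'   Event times in seconds, or `NA`.
#' @param aborted,occluded Logical flags.
#' @return A list of class `session_events`.
#' @export
session_events <- function(seal_found_t = NA_real_,
                           sweep_start_notify_t = NA_real_,
                           sweep_end_notify_t = NA_real_,
                           seal_lost_t = NA_real_,
                           aborted = FALSE, occluded = FALSE) {
  ev <- list(seal_found_t = as.numeric(seal_found_t %||% NA_real_),
             sweep_start_notify_t = as.numeric(sweep_start_notify_t %||% NA_real_),
             sweep_end_notify_t = as.numeric(sweep_end_notify_t %||% NA_real_),
             seal_lost_t = as.numeric(seal_lost_t %||% NA_real_),
             aborted = isTRUE(aborted), occluded = isTRUE(occluded))
  if (!is.na(ev$sweep_start_notify_t) && !is.na(ev$sweep_end_notify_t) &&
      ev$sweep_start_notify_t >= ev$sweep_end_notify_t)
    validation_error("sweep_start_notify_t must precede sweep_end_notify_t")
  structure(ev, class = "session_events")
}

# Canonical tympanogram pressure grid: -400..+200 daPa in 5 daPa steps.
tymp_grid <- function() seq(-400, 200, by = 5)

#' Construct a tympanogram
#'
#' Admittance (mL equivalent volume) on the canonical 5 daPa pressure grid
#' spanning -400 to +200 daPa, stored in ascending pressure order.
#'
#' @param data Data frame with columns `pressure_daPa` (ascending, constant
#'   5 daPa spacing) and `admittance_mL`.
#' @param calibrated Logical: are admittance values in calibrated mL units?
#'   Calibrated admittance must be finite and non-negative.
#' @return A tibble of class `tympanogram` with attribute `calibrated`.
#' @examples
#' flat <- tympanogram(data.frame(pressure_daPa = seq(-400, 200, 5),
#'                                admittance_mL = 1.2))
#' @export
tympanogram <- function(data, calibrated = TRUE) {
  if (!is.data.frame(data) ||
      !all(c("pressure_daPa", "admittance_mL") %in% names(data)))
    validation_error("tympanogram needs columns pressure_daPa and admittance_mL")
  if (nrow(data) < 1L) validation_error("tympanogram grid is empty")
  p <- data$pressure_daPa; y <- data$admittance_mL
  if (nrow(data) > 1L) {
    dp <- diff(p)
    if (any(abs(dp - 5) > 1e-9))
      validation_error("pressure grid must ascend in constant 5 daPa steps")
  }
  if (anyNA(y) || any(!is.finite(y)))
    validation_error("admittance values must be finite")
  if (isTRUE(calibrated) && any(y < -1e-9))
    validation_error("calibrated admittance must be non-negative")
  out <- tibble::tibble(pressure_daPa = as.numeric(p), admittance_mL = as.numeric(y))
  attr(out, "calibrated") <- isTRUE(calibrated)
  class(out) <- c("tympanogram", class(out))
  out
}

#' Tympanogram clinical metrics
#'
#' @param peak_admittance Baseline-compensated peak admittance (mL).
#' @param peak_pressure Tympanometric peak pressure (daPa).
#' @param ear_canal_volume Equivalent volume at +200 daPa (mL).
#' @param is_flat Flat (Type-B-like) curve flag.
#' @param peak_admittance_absolute Uncompensated maximum admittance (mL).
#' @return A one-row tibble of class `tymp_metrics`.
#' @export
tymp_metrics <- function(peak_admittance, peak_pressure, ear_canal_volume,
                         is_flat, peak_admittance_absolute = NA_real_) {
  if (ear_canal_volume < -1e-9)
    validation_error("ear_canal_volume must be non-negative")
  out <- tibble::tibble(
    peak_admittance = as.numeric(peak_admittance),
    peak_pressure = as.numeric(peak_pressure),
    ear_canal_volume = as.numeric(ear_canal_volume),
    is_flat = isTRUE(is_flat),
    peak_admittance_absolute = as.numeric(peak_admittance_absolute))
  class(out) <- c("tymp_metrics", class(out))
  out
}

#' Device calibration model
#'
#' Cubic coefficients mapping an uncalibrated probe-tone amplitude `x` to mL
#' equivalent volume via `p1*x^3 + p2*x^2 + p3*x + p4`, plus the
#' slope-compensation line fitted to the calibrated 0 mL cavity curve:
#' slope `m` (mL/daPa) and `b`, the line's value at -400 daPa. The
#' compensation subtracted at pressure p is `m * (p + 400) + b`.
#'
#' @param p1,p2,p3,p4 Cubic coefficients (cubic term first).
#' @param m Slope of the 0 mL compensation line (mL per daPa).
#' @param b Value of the compensation line at -400 daPa (mL).
#' @param gain_setting Speaker volume gain that produces 85 dB SPL output.
#' @param amplitude_range Amplitude interval the cubic was fitted over
#'   (used for the monotonicity check); optional.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(p1, p2, p3, p4, m = 0, b = 0, gain_setting = 85,
                              amplitude_range = NULL) {
  for (v in list(p1, p2, p3, p4, m, b, gain_setting))
    if (!is_number(v)) schema_error("calibration coefficients must be numeric scalars")
  obj <- structure(
    list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, m = m, b = b,
         gain_setting = gain_setting,
         amplitude_range = amplitude_range),
    class = "calibration_model")
  if (!is.null(amplitude_range) && !calibration_is_monotone(obj))
    rlang::warn("calibration cubic is not monotone over the fitted amplitude range",
                class = "tymp_calibration_warning")
  obj
}

# Numeric monotonicity check of the cubic over the fitted amplitude interval.
calibration_is_monotone <- function(cal, n = 400L) {
  rng <- cal$amplitude_range
  if (is.null(rng)) return(NA)
  x <- seq(rng[1], rng[2], length.out = n)
  v <- cal$p1 * x^3 + cal$p2 * x^2 + cal$p3 * x + cal$p4
  all(diff(v) < 0) || all(diff(v) > 0)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>\n")
  cat(sprintf("  cubic: %.6g x^3 + %.6g x^2 + %.6g x + %.6g\n",
              x$p1, x$p2, x$p3, x$p4))
  cat(sprintf("  slope line: m = %.6g mL/daPa, b(-400) = %.6g mL\n", x$m, x$b))
  cat(sprintf("  gain_setting: %g\n", x$gain_setting))
  invisible(x)
}

# Evaluate the cubic amplitude -> mL map.
calibration_map <- function(cal, x) {
  cal$p1 * x^3 + cal$p2 * x^2 + cal$p3 * x + cal$p4
}

# Slope-compensation line value at pressure p (line anchored at -400 daPa).
calibration_comp_line <- function(cal, p) cal$m * (p + 400) + cal$b

#' Bundle a measurement session
#'
#' @param audio An [audio_trace()].
#' @param pressure A [pressure_trace()].
#' @param events A [session_events()].
#' @param motor Optional tibble `time_s`, `displacement_mm` of plunger travel.
#' @param truth Optional simulator ground truth (list).
#' @return A list of class `tymp_session`.
#' @export
tymp_session <- function(audio, pressure, events, motor = NULL, truth = NULL) {
  stopifnot(inherits(audio, "audio_trace"), inherits(pressure, "pressure_trace"),
            inherits(events, "session_events"))
  structure(list(audio = audio, pressure = pressure, events = events,
                 motor = motor, truth = truth),
            class = "tymp_session")
}

#' @export
print.tymp_session <- function(x, ...) {
  cat("<tymp_session>\n")
  print(x$audio)
  cat(sprintf("  pressure: %d samples over %.2f s\n", nrow(x$pressure),
              diff(range(x$pressure$time_s))))
  if (!is.null(x$truth))
    cat(sprintf("  simulated scenario: %s\n", x$truth$scenario %||% "?"))
  invisible(x)
}
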
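# Synchronized session -> tympanogram. The audio between the refined sweep
# boundaries is cut into N segments (N = pressure samples in the sweep), the
# probe-tone amplitude of each segment is read off a single 24000-point FFT
# bin (1 Hz bins at 24 kHz), calibrated to mL, binned to the canonical
# 5 daPa grid, and smoothed with a window-5 moving average.

#' Extract the raw amplitude-vs-pressure curve
#'
#' Divides the audio between `t3` and `t5` into `N` equal segments, where `N`
#' is the number of pressure samples recorded inside the sweep; each segment
#' is zero-padded to `n_fft` samples and the probe-tone bin magnitude is
#' tracked across segments, paired with the i-th sweep pressure value.
#'
#' A guard interval of `trim` seconds is discarded at the sweep boundaries:
#' the motor-reversal transient (the dip and rebound around each turning
#' point) contaminates the tone amplitude there, and the 5 daPa binning
#' refills the few affected edge bins from their neighbours. The transient
#' is asymmetric about each reversal — the rebound runs into the first
#' ~40 ms of the sweep, the next dip starts ~85 ms before its end — so the
#' default guard is shorter at the start than at the end.
#'
#' @param s A [synchronize()] result.
#' @param a The session's [audio_trace()].
#' @param freq Probe-tone frequency in Hz (default 226).
#' @param n_fft FFT length (default 24000; 1 Hz bins at 24 kHz).
#' @param trim Guard interval excluded at the sweep start and end, s; a
#'   length-2 vector `c(start, end)` (default `c(0.05, 0.10)`), or one value
#'   used for both.
#' @return A tibble with columns `pressure_daPa`, `amplitude` (uncalibrated
#'   bin magnitude).
#' @export
extract_raw_curve <- function(s, a, freq = 226, n_fft = 24000,
                              trim = c(0.05, 0.10)) {
  stopifnot(inherits(s, "synced_streams"), inherits(a, "audio_trace"))
  trim <- rep_len(trim, 2L)
  pr <- s$pressure
  in_sweep <- pr$time_s >= s$t3 + trim[1] & pr$time_s <= s$t5 - trim[2]
  n <- sum(in_sweep)
  if (n < 10L)
    insufficient_data("fewer than 10 pressure samples inside the sweep")
  fs <- a$sample_rate
  i0 <- max(1L, floor((s$t3 + trim[1]) * fs) + 1L)
  i1 <- min(length(a$samples), floor((s$t5 - trim[2]) * fs))
  if (i1 <= i0) sync_error("audio does not cover the sweep interval")
  total <- i1 - i0 + 1L
  bounds <- i0 + round((0:n) * (total / n))
  amp <- vapply(seq_len(n), function(i) {
    seg <- a$samples[bounds[i]:(bounds[i + 1] - 1L)]
    tone_bin_magnitude(seg, freq = freq, sample_rate = fs, n_fft = n_fft)
  }, numeric(1))
  tibble::tibble(pressure_daPa = pr$pressure_daPa[in_sweep], amplitude = amp)
}

#' Calibrate a raw amplitude curve to mL equivalent volume
#'
#' Applies the cubic normalization `p1*x^3 + p2*x^2 + p3*x + p4` to each
#' amplitude, then subtracts the slope-compensation line (anchored at
#' -400 daPa) fitted to the 0 mL cavity curve.
#'
#' @param curve Tibble from [extract_raw_curve()] (`pressure_daPa`,
#'   `amplitude`).
#' @param cal A [calibration_model()].
#' @return A tibble with columns `pressure_daPa`, `admittance_mL`.
#' @export
apply_calibration <- function(curve, cal) {
  stopifnot(inherits(cal, "calibration_model"))
  if (!all(c("pressure_daPa", "amplitude") %in% names(curve)))
    validation_error("curve needs columns pressure_daPa and amplitude")
  y <- calibration_map(cal, curve$amplitude) -
    calibration_comp_line(cal, curve$pressure_daPa)
  if (mean(y < -0.1) > 0.10)
    rlang::warn("more than 10% of calibrated points are below -0.1 mL; calibration may not match this device",
                class = "tymp_calibration_warning")
  tibble::tibble(pressure_daPa = curve$pressure_daPa, admittance_mL = y)
}

#' Smooth a calibrated curve onto the canonical tympanogram grid
#'
#' Two-part smoothing: admittance values are averaged within 5 daPa pressure
#' bins on the -400..+200 grid; empty bins are filled with the mean of the
#' nearest non-empty bin on each side (the single neighbour at the edges);
#' the binned curve is then passed through a centred moving-average filter of
#' window 5 bins, truncated at the edges. Calibrated output is clamped at 0
#' (admittance cannot be negative).
#'
#' @param curve Tibble with columns `pressure_daPa`, `admittance_mL` (at
#'   least 10 points inside the grid span).
#' @param calibrated Calibrated flag for the result (default TRUE).
#' @return A [tympanogram()] on the 121-point grid.
#' @export
smooth_tympanogram <- function(curve, calibrated = TRUE) {
  if (!all(c("pressure_daPa", "admittance_mL") %in% names(curve)))
    validation_error("curve needs columns pressure_daPa and admittance_mL")
  grid <- tymp_grid()
  inside <- curve$pressure_daPa >= -402.5 & curve$pressure_daPa <= 202.5
  if (sum(inside) < 10L)
    insufficient_data("fewer than 10 points inside the tympanogram span")
  p <- curve$pressure_daPa[inside]; y <- curve$admittance_mL[inside]
  bin <- round((p + 400) / 5) + 1L
  bin <- pmin(pmax(bin, 1L), length(grid))
  sums <- tapply(y, bin, mean)
  vals <- rep(NA_real_, length(grid))
  vals[as.integer(names(sums))] <- as.numeric(sums)
  filled <- which(!is.na(vals))
  if (!length(filled)) insufficient_data("all tympanogram bins are empty")
  for (i in which(is.na(vals))) {
    left <- filled[filled < i]; right <- filled[filled > i]
    neigh <- c(if (length(left)) vals[max(left)],
               if (length(right)) vals[min(right)])
    vals[i] <- mean(neigh)
  }
  # centred moving average, window 5, truncated at the edges
  n <- length(vals)
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
    mean(vals[lo:hi])
  }, numeric(1))
  if (isTRUE(calibrated)) sm <- pmax(sm, 0)
  tympanogram(tibble::tibble(pressure_daPa = grid, admittance_mL = sm),
              calibrated = calibrated)
}

#' Clinical metrics of a tympanogram
#'
#' Ear canal volume is the admittance at +200 daPa (where the eardrum is
#' stiffened and the probe sees essentially the canal); peak pressure is the
#' grid pressure of maximum admittance (ties broken towards 0 daPa); peak
#' admittance is the baseline-compensated maximum (max minus the +200 daPa
#' value); a curve whose compensated peak stays below 0.1 mL is flagged flat.
#'
#' @param t A calibrated [tympanogram()].
#' @param flat_threshold Compensated-peak threshold for flatness, mL
#'   (default 0.1).
#' @return A [tymp_metrics()] one-row tibble.
#' @export
compute_metrics <- function(t, flat_threshold = 0.1) {
  if (!inherits(t, "tympanogram")) t <- tympanogram(t)
  ecv <- t$admittance_mL[which(t$pressure_daPa == 200)]
  if (!length(ecv)) domain_error("tympanogram does not reach +200 daPa")
  peak_abs <- max(t$admittance_mL)
  at_max <- which(abs(t$admittance_mL - peak_abs) < 1e-12)
  peak_p <- t$pressure_daPa[at_max[which.min(abs(t$pressure_daPa[at_max]))]]
  peak <- peak_abs - ecv
  tymp_metrics(peak_admittance = peak, peak_pressure = peak_p,
               ear_canal_volume = ecv, is_flat = peak < flat_threshold,
               peak_admittance_absolute = peak_abs)
}

#' Full analysis of a recorded session
#'
#' Convenience pipeline: [synchronize()], [extract_raw_curve()],
#' [apply_calibration()], [smooth_tympanogram()], [compute_metrics()].
#'
#' @param session A [tymp_session()].
#' @param cal A [calibration_model()].
#' @param freq Probe-tone frequency in Hz.
#' @return A list of class `tymp_analysis`: `tympanogram`, `metrics`,
#'   `synced`.
#' @export
analyze_session <- function(session, cal, freq = 226) {
  stopifnot(inherits(session, "tymp_session"))
  synced <- synchronize(session$audio, session$pressure, session$events)
  raw <- extract_raw_curve(synced, session$audio, freq = freq)
  cald <- apply_calibration(raw, cal)
  tymp <- smooth_tympanogram(cald)
  structure(list(tympanogram = tymp, metrics = compute_metrics(tymp),
                 synced = synced),
            class = "tymp_analysis")
}

#' @export
print.tymp_analysis <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<tymp_analysis> peak %.2f mL @ %+d daPa, ECV %.2f mL%s\n",
              m$peak_admittance, as.integer(m$peak_pressure),
              m$ear_canal_volume, if (m$is_flat) " [flat]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.tymp_analysis <- function(x, ...) {
  out <- x$metrics
  class(out) <- class(tibble::tibble())
  out
}
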
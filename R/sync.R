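# Align the pressure record to the audio record. The microcontroller's sweep
# boundary notifications arrive with unknown Bluetooth delay; the acoustic
# envelope dips briefly at each pressure-direction change, so the true
# turning instants are recovered by searching the envelope in the 500 ms
# before each notification, and the pressure clock is then remapped affinely
# so its max/min-pressure instants coincide with the refined times.

#' Band-limited amplitude envelope of an audio trace
#'
#' Band-passes the audio to the probe-tone band (4th-order Butterworth,
#' zero-phase) and reports the RMS level per non-overlapping frame.
#'
#' The default frame holds exactly two periods of the 226 Hz probe tone
#' (212 samples at 24 kHz, about 8.8 ms): over an integer number of
#' half-periods the RMS of a sinusoid is independent of its starting phase,
#' so the envelope carries no frame-phase ripple and sub-frame features
#' remain localizable. A 10 ms frame (2.26 tone periods) would ripple by
#' several percent frame to frame.
#'
#' @param a An [audio_trace()].
#' @param band Pass band in Hz (default `c(220, 230)`).
#' @param frame_length Frame length in seconds (default 212/24000; sets the
#'   time resolution of everything built on the envelope).
#' @return A tibble of class `tymp_envelope` with columns `frame_time` (frame
#'   centres, s) and `level` (RMS amplitude, full-scale units).
#' @export
compute_envelope <- function(a, band = c(220, 230), frame_length = 212 / 24000) {
  stopifnot(inherits(a, "audio_trace"))
  L <- max(1L, round(frame_length * a$sample_rate))
  if (length(a$samples) < L)
    insufficient_data("audio shorter than one envelope frame")
  y <- bandpass_filter(a$samples, band, a$sample_rate)
  n_frames <- length(y) %/% L
  idx <- seq_len(n_frames * L)
  m <- matrix(y[idx]^2, nrow = L)
  levels <- sqrt(colMeans(m))
  out <- tibble::tibble(
    frame_time = (seq_len(n_frames) - 0.5) * L / a$sample_rate,
    level = levels)
  attr(out, "frame_length") <- L / a$sample_rate
  attr(out, "band") <- band
  class(out) <- c("tymp_envelope", class(out))
  out
}

#' Refine a sweep-boundary notification against the envelope
#'
#' Searches the envelope from 500 ms before the notification to the
#' notification for the most prominent local minimum (the turning-point dip),
#' then returns the time of
#' the maximum envelope value between that dip and the notification — the
#' instant of maximum (`kind = "max_pressure"`, point 3) or minimum
#' (`kind = "min_pressure"`, point 5) pressure. If no qualifying dip exists
#' the notification time is returned unchanged with a warning.
#'
#' Prominence is measured against the envelope maximum to the candidate
#' minimum's right — the dip is a drop below its own recovery peak — and
#' must reach 10% of the window median. A right-sided measure is the stable
#' one here: when the notification arrives late, the window's left edge can
#' clip the dip's onset, but the recovery peak that follows the dip is
#' always inside the window.
#'
#' @param e A [compute_envelope()] result.
#' @param t_notify Notification time in s.
#' @param kind `"max_pressure"` or `"min_pressure"` (labels the boundary; the
#'   search is identical).
#' @return Refined boundary time in s.
#' @export
refine_boundary <- function(e, t_notify,
                            kind = c("max_pressure", "min_pressure")) {
  kind <- match.arg(kind)
  stopifnot(inherits(e, "tymp_envelope"))
  sel <- which(e$frame_time >= t_notify - 0.5 & e$frame_time <= t_notify)
  if (length(sel) < 3L)
    domain_error("the 500 ms search window is not covered by the envelope")
  lv <- e$level[sel]
  med <- stats::median(lv)
  n <- length(lv)
  interior <- 2:(n - 1)
  is_min <- lv[interior] <= lv[interior - 1] & lv[interior] <= lv[interior + 1]
  cand <- interior[is_min]
  if (length(cand)) {
    prom <- vapply(cand, function(i) max(lv[i:n]) - lv[i], numeric(1))
    keep <- prom >= 0.1 * med
    cand <- cand[keep]; prom <- prom[keep]
  }
  if (!length(cand)) {
    rlang::warn(sprintf("no envelope dip before the %s notification; falling back to the notification time", kind),
                class = "tymp_sync_warning")
    return(t_notify)
  }
  dip <- cand[which.max(prom)]
  after <- dip:n
  e$frame_time[sel[after[which.max(lv[after])]]]
}

#' Synchronize the pressure record to the audio clock
#'
#' Refines both sweep-boundary notifications with [refine_boundary()], then
#' remaps the pressure timestamps affinely so the trace's own max- and
#' min-pressure instants land on the refined `t3` and `t5`. The affine map
#' preserves sample order and count. `N`, the number of pressure samples
#' falling inside the sweep, fixes the audio segmentation downstream.
#'
#' @param a An [audio_trace()].
#' @param p A [pressure_trace()].
#' @param ev A [session_events()] with both sweep notifications present.
#' @param envelope Optional precomputed [compute_envelope()] result.
#' @return A list of class `synced_streams`: `t3`, `t5` (s, audio clock),
#'   `pressure` (remapped [pressure_trace()]), `n_sweep_samples`, and the
#'   remap coefficients `remap = c(intercept, slope)`.
#' @export
synchronize <- function(a, p, ev, envelope = NULL) {
  stopifnot(inherits(a, "audio_trace"), inherits(p, "pressure_trace"),
            inherits(ev, "session_events"))
  if (is.na(ev$sweep_start_notify_t) || is.na(ev$sweep_end_notify_t))
    sync_error("both sweep notifications are required for synchronization")
  e <- envelope %||% compute_envelope(a)
  t3 <- refine_boundary(e, ev$sweep_start_notify_t, "max_pressure")
  t5 <- refine_boundary(e, ev$sweep_end_notify_t, "min_pressure")
  if (t3 >= t5) sync_error("refined sweep boundaries are out of order")

  tp3 <- p$time_s[which.max(p$pressure_daPa)]
  tp5 <- p$time_s[which.min(p$pressure_daPa)]
  if (tp3 >= tp5) sync_error("pressure trace max does not precede its min")
  slope <- (t5 - t3) / (tp5 - tp3)
  new_t <- t3 + slope * (p$time_s - tp3)
  remapped <- pressure_trace(tibble::tibble(time_s = new_t,
                                            pressure_daPa = p$pressure_daPa))
  in_sweep <- new_t >= t3 & new_t <= t5
  structure(list(t3 = t3, t5 = t5, pressure = remapped,
                 n_sweep_samples = sum(in_sweep),
                 remap = c(intercept = t3 - slope * tp3, slope = slope)),
            class = "synced_streams")
}

#' @export
print.synced_streams <- function(x, ...) {
  cat(sprintf("<synced_streams> t3 = %.3f s, t5 = %.3f s, N = %d sweep samples\n",
              x$t3, x$t5, x$n_sweep_samples))
  invisible(x)
}
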
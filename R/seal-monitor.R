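# Seal / occlusion / abort decisions from streaming pressure and audio.
# Replays the device protocol offline: successive step-duration windows are
# rated for pressure change (seal probe), a candidate seal is screened for
# occlusion on the reflected tone level, and the measurement phase is watched
# for seal loss (pressure back at ambient while the commanded target is far)
# and for the 16 mm forward-travel safety abort.

#' Seal-monitor configuration
#'
#' @param seal_rate_threshold Pressure-rise rate that indicates a seal, in
#'   daPa/s. Must be at least 17 (the minimum workable threshold; rates near
#'   2 daPa/s are seen with the probe in open air).
#' @param occlusion_level_threshold Reflected-tone level above which the tip
#'   is called occluded, in dB SPL-equivalent (default 65).
#' @param step_size,step_duration Seal-probe step geometry (mm, s).
#' @param max_forward_travel Abort limit on forward plunger travel, mm.
#' @param start_pressure,end_pressure Sweep endpoints in daPa.
#' @param seal_loss_band Pressure band around ambient (daPa) that counts as
#'   "returned to ambient" for seal-loss detection (default 10).
#' @param occlusion_window Audio window used for the occlusion check, s.
#' @return A list of class `seal_config`.
#' @export
seal_config <- function(seal_rate_threshold = 17, occlusion_level_threshold = 65,
                        step_size = 0.5, step_duration = 1.19,
                        max_forward_travel = 16, start_pressure = 200,
                        end_pressure = -400, seal_loss_band = 10,
                        occlusion_window = 0.3) {
  if (seal_rate_threshold < 17)
    validation_error("seal_rate_threshold must be at least 17 daPa/s")
  if (occlusion_level_threshold <= 0 || seal_loss_band <= 0)
    validation_error("thresholds must be positive")
  structure(list(seal_rate_threshold = seal_rate_threshold,
                 occlusion_level_threshold = occlusion_level_threshold,
                 step_size = step_size, step_duration = step_duration,
                 max_forward_travel = max_forward_travel,
                 start_pressure = start_pressure, end_pressure = end_pressure,
                 seal_loss_band = seal_loss_band,
                 occlusion_window = occlusion_window),
            class = "seal_config")
}

#' Pressure-change rate over a time window
#'
#' Least-squares slope of pressure versus time over `window`, the robust
#' replacement for endpoint differencing on a noisy sensor.
#'
#' @param p A [pressure_trace()].
#' @param window Numeric `c(t0, t1)` in the trace's clock.
#' @return Rate in daPa/s.
#' @examples
#' tr <- pressure_trace(data.frame(time_s = 0:10 / 10,
#'                                 pressure_daPa = 2.03 * 0:10 / 10))
#' step_rate(tr, c(0, 1)) # 2.03
#' @export
step_rate <- function(p, window) {
  stopifnot(inherits(p, "pressure_trace"), length(window) == 2L)
  sel <- p$time_s >= window[1] & p$time_s <= window[2]
  if (sum(sel) < 2L)
    insufficient_data("step_rate needs at least 2 samples in the window")
  ls_slope(p$time_s[sel], p$pressure_daPa[sel])
}

#' Seal decision from a measured pressure rate
#'
#' Sealed iff the rate strictly exceeds the threshold ("exceed" is strict:
#' a rate exactly at threshold is still no seal).
#'
#' @param rate Measured rate in daPa/s.
#' @param cfg A [seal_config()].
#' @return `"sealed"` or `"no_seal"`.
#' @export
decide_seal <- function(rate, cfg = seal_config()) {
  if (!is_number(rate)) validation_error("rate must be a finite number")
  if (rate > cfg$seal_rate_threshold) "sealed" else "no_seal"
}

#' Occlusion check on the reflected tone
#'
#' Band-limits the audio to the probe-tone band (220-230 Hz), estimates the
#' tone amplitude from the RMS over `window`, converts to dB SPL-equivalent
#' via the trace's full-scale reference, and calls the tip occluded iff the
#' level strictly exceeds the threshold.
#'
#' @param a An [audio_trace()].
#' @param window Numeric `c(t0, t1)` on the audio clock; at least 100 ms.
#' @param cfg A [seal_config()].
#' @param band Analysis band in Hz (default `c(220, 230)`).
#' @return `"occluded"` or `"clear"`, with the measured level (dB) in
#'   attribute `level_db`.
#' @export
check_occlusion <- function(a, window, cfg = seal_config(),
                            band = c(220, 230)) {
  stopifnot(inherits(a, "audio_trace"), length(window) == 2L)
  if (diff(window) < 0.1 - 1e-9)
    insufficient_data("occlusion check needs at least 100 ms of audio")
  i0 <- max(1L, floor(window[1] * a$sample_rate) + 1L)
  i1 <- min(length(a$samples), floor(window[2] * a$sample_rate))
  if (i1 - i0 + 1L < 0.1 * a$sample_rate)
    insufficient_data("occlusion window extends beyond the recording")
  seg <- bandpass_filter(a$samples[i0:i1], band, a$sample_rate)
  amp <- sqrt(mean(seg^2)) * sqrt(2)
  level <- amplitude_to_db(amp, a$level_reference)
  verdict <- if (level > cfg$occlusion_level_threshold) "occluded" else "clear"
  structure(verdict, level_db = level)
}

# Fallback travel estimate when no motor record exists: gas-law displacement
# implied by the observed pressure, assuming a sealed ~1 mL + dead volume.
estimate_travel <- function(p_daPa, pneu, coupled_volume = 1) {
  area <- syringe_area_ml_mm(pneu)
  v0 <- coupled_volume + pneu$dead_volume
  (v0 / area) * p_daPa / (pneu$ambient_pressure + p_daPa)
}

#' Run the seal monitor over a recorded session
#'
#' Replays the acquisition protocol on a recorded (or simulated) session:
#' successive `step_duration` windows are rated with [step_rate()] until
#' [decide_seal()] fires, the candidate seal is screened with
#' [check_occlusion()], and the measurement phase is then watched sample by
#' sample for seal loss (pressure within `seal_loss_band` of ambient while
#' the commanded sweep target is 50 daPa or more away) and for the forward
#' travel crossing `max_forward_travel`. Travel accounting uses the session's
#' motor displacement record when available, else a gas-law estimate from
#' pressure.
#'
#' @param session A [tymp_session()], or a [pressure_trace()] (then supply
#'   `audio`).
#' @param audio An [audio_trace()] when `session` is a pressure trace.
#' @param pneu A [pneumatic_config()].
#' @param cfg A [seal_config()].
#' @param motor Optional motor displacement tibble (`time_s`,
#'   `displacement_mm`); taken from the session when present.
#' @return A list of class `seal_monitor_result`: `verdicts` (tibble with
#'   columns `state`, `evidence`, `at_time`, `travel_mm`), `events`
#'   (a [session_events()]), and `outcome` — the terminal state, one of
#'   `no_seal`, `sealed`, `occluded`, `seal_lost`, `aborted`.
#' @export
run_monitor <- function(session, audio = NULL, pneu = pneumatic_config(),
                        cfg = seal_config(), motor = NULL) {
  if (inherits(session, "tymp_session")) {
    pressure <- session$pressure
    audio <- session$audio
    motor <- motor %||% session$motor
  } else {
    pressure <- session
    if (is.null(audio)) validation_error("run_monitor needs an audio trace")
  }
  stopifnot(inherits(pressure, "pressure_trace"), inherits(audio, "audio_trace"))

  tt <- pressure$time_s; pp <- pressure$pressure_daPa
  travel_at <- if (!is.null(motor)) {
    function(t) stats::approx(motor$time_s, motor$displacement_mm, t,
                              rule = 2)$y
  } else {
    function(t) estimate_travel(
      stats::approx(tt, pp, t, rule = 2)$y, pneu)
  }
  t_abort <- NA_real_
  if (!is.null(motor)) {
    over <- which(motor$displacement_mm > cfg$max_forward_travel)
    if (length(over)) t_abort <- motor$time_s[over[1]]
  }

  verdicts <- list()
  add <- function(state, evidence, at_time) {
    verdicts[[length(verdicts) + 1L]] <<- tibble::tibble(
      state = state, evidence = evidence, at_time = at_time,
      travel_mm = travel_at(at_time))
  }
  finish <- function(outcome, events) {
    list_out <- list(
      verdicts = dplyr::bind_rows(verdicts),
      events = events, outcome = outcome)
    structure(list_out, class = "seal_monitor_result")
  }

  ## phase 1: probe windows until a seal fires
  w <- cfg$step_duration
  t0 <- tt[1]
  t_sealed <- NA_real_
  k <- 0L
  while (t0 + (k + 1) * w <= tt[length(tt)]) {
    win <- c(t0 + k * w, t0 + (k + 1) * w)
    rate <- step_rate(pressure, win)
    if (!is.na(t_abort) && t_abort <= win[2]) {
      add("aborted", travel_at(t_abort), t_abort)
      return(finish("aborted", session_events(aborted = TRUE)))
    }
    if (decide_seal(rate, cfg) == "sealed") {
      t_sealed <- win[2]
      add("sealed", rate, t_sealed)
      break
    }
    add("no_seal", rate, win[2])
    k <- k + 1L
  }
  if (is.na(t_sealed)) return(finish("no_seal", session_events()))

  ## phase 2: occlusion screen on the reflected tone
  occ_win <- c(t_sealed, t_sealed + cfg$occlusion_window)
  occ <- tryCatch(check_occlusion(audio, occ_win, cfg),
                  tymp_insufficient_data_error = function(e) {
                    structure("clear", level_db = NA_real_)
                  })
  if (identical(as.character(occ), "occluded")) {
    add("occluded", attr(occ, "level_db"), occ_win[2])
    return(finish("occluded",
                  session_events(seal_found_t = t_sealed, occluded = TRUE)))
  }

  ## phase 3: pressurize, sweep, watch for loss / abort
  after <- which(tt > t_sealed)
  sweep_dur <- (cfg$start_pressure - cfg$end_pressure) / pneu$sweep_speed
  t3_obs <- NA_real_
  max_p <- -Inf
  for (i in after) {
    if (!is.na(t_abort) && tt[i] >= t_abort) {
      add("aborted", travel_at(t_abort), t_abort)
      return(finish("aborted",
                    session_events(seal_found_t = t_sealed, aborted = TRUE)))
    }
    max_p <- max(max_p, pp[i])
    if (is.na(t3_obs)) {
      if (pp[i] >= cfg$start_pressure - 5) t3_obs <- tt[i]
      # loss during pressurization: had built pressure, back at ambient
      if (max_p > 100 && abs(pp[i]) < cfg$seal_loss_band) {
        add("seal_lost", pp[i], tt[i])
        return(finish("seal_lost",
                      session_events(seal_found_t = t_sealed,
                                     seal_lost_t = tt[i])))
      }
    } else {
      el <- tt[i] - t3_obs
      if (el > sweep_dur) break                  # sweep complete
      expected <- cfg$start_pressure - pneu$sweep_speed * el
      if (expected <= -50 && abs(pp[i]) < cfg$seal_loss_band) {
        add("seal_lost", pp[i], tt[i])
        return(finish("seal_lost",
                      session_events(seal_found_t = t_sealed,
                                     sweep_start_notify_t = t3_obs,
                                     seal_lost_t = tt[i])))
      }
      if (pp[i] <= cfg$end_pressure + 5) break   # reached -400
    }
  }
  if (is.na(t3_obs)) {
    # never reached the start pressure and never aborted/lost: stalled
    return(finish("no_seal", session_events(seal_found_t = t_sealed)))
  }
  sweep <- which(tt >= t3_obs & tt <= t3_obs + sweep_dur + 0.5)
  t5_obs <- tt[sweep[which.min(pp[sweep])]]
  ev <- session_events(seal_found_t = t_sealed,
                       sweep_start_notify_t = tt[which.max(pp)],
                       sweep_end_notify_t = t5_obs)
  add("sealed", max_p, t5_obs)
  finish("sealed", ev)
}

#' @export
print.seal_monitor_result <- function(x, ...) {
  cat(sprintf("<seal_monitor_result> outcome: %s (%d verdicts)\n",
              x$outcome, nrow(x$verdicts)))
  invisible(x)
}
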
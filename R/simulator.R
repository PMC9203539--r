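# Forward model of the pneumatic-acoustic measurement. Pressure follows the
# isothermal gas law for the syringe + tubing + coupled (ear/cavity) air
# volume; unsealed probes leak with a first-order time constant; the 226 Hz
# probe tone is re-emitted with an amplitude that decreases monotonically in
# the equivalent volume seen by the probe. Sessions are generated on a
# scripted protocol (probe-out baseline, insertion, seal probe, occlusion
# window, fast pressurization, slow sweep, fast return) with known ground
# truth, so every downstream stage can be tested without hardware.

# Leak time constant (s) that makes a 0.5 mm / 1.19 s probe step into an
# unsealed system register ~2.03 daPa/s (solved by root-finding on the
# generator's own leaky step response).
NO_SEAL_LEAK_TAU <- 0.1288

# Unit Hann pulse of a given centre and width.
hann_pulse <- function(x, center, width) {
  u <- (x - center) / width + 0.5
  ifelse(u >= 0 & u <= 1, 0.5 - 0.5 * cos(2 * pi * u), 0)
}

#' Pneumatic configuration
#'
#' Geometry and speeds of the syringe-driven pressure system. The default
#' `dead_volume` is set so that, with a 1 mL ear coupled, a full +200 to
#' -400 daPa sweep displaces the 12.5 mm plunger by 5.3 mm under the
#' isothermal gas law.
#'
#' @param syringe_diameter Plunger diameter in mm (default 12.5).
#' @param dead_volume Tubing + probe air volume in mL (default 9.76).
#' @param max_forward_travel Safety abort limit on forward plunger travel, mm.
#' @param step_size Seal-probe step in mm (default 0.5).
#' @param step_duration Seal-probe step duration in s (default 1.19).
#' @param fast_speed Pressurization/return speed in daPa/s (default 316).
#' @param sweep_speed Measurement sweep speed in daPa/s (default 123).
#' @param leak_time_constant First-order leak time constant in s
#'   (`Inf` = sealed).
#' @param ambient_pressure Absolute ambient pressure in daPa (default 10132.5).
#' @param sensor_rate Pressure sensor sampling rate in Hz (default 45.2, one
#'   sample per five probe-tone periods; see the methods vignette for why the
#'   rate is chosen commensurate with the tone).
#' @return A list of class `pneumatic_config`.
#' @export
pneumatic_config <- function(syringe_diameter = 12.5, dead_volume = 9.76,
                             max_forward_travel = 16, step_size = 0.5,
                             step_duration = 1.19, fast_speed = 316,
                             sweep_speed = 123, leak_time_constant = Inf,
                             ambient_pressure = 10132.5, sensor_rate = 45.2) {
  vals <- list(syringe_diameter = syringe_diameter, dead_volume = dead_volume,
               max_forward_travel = max_forward_travel, step_size = step_size,
               step_duration = step_duration, fast_speed = fast_speed,
               sweep_speed = sweep_speed, leak_time_constant = leak_time_constant,
               ambient_pressure = ambient_pressure, sensor_rate = sensor_rate)
  for (nm in names(vals))
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L || vals[[nm]] <= 0)
      validation_error(paste0("pneumatic_config$", nm, " must be a positive number"))
  if (step_size >= max_forward_travel)
    validation_error("step_size must be smaller than max_forward_travel")
  structure(vals, class = "pneumatic_config")
}

# Plunger cross-section in mL per mm of travel.
syringe_area_ml_mm <- function(pneu) pi * (pneu$syringe_diameter / 2)^2 / 1000

#' Noise and imperfection configuration
#'
#' Everything that separates an ideal session from a realistic one: sensor and
#' microphone noise, Bluetooth notification jitter, the brief acoustic
#' reversal transient at the sweep turning points (a dip of depth `dip_depth`
#' lasting `dip_duration` just before the reversal, followed by a rebound
#' overshoot whose crest marks the reversal instant), a slow multiplicative
#' amplitude drift across the sweep (the slope artifact the calibration's
#' compensation line removes), and the constant offset between the
#' pressure-sensor clock and the audio clock. `noise_preset("none")` zeroes
#' all of these except the reversal transient, giving exactly reproducible
#' ideal sessions.
#'
#' @param pressure_noise_sd Pressure sensor noise SD in daPa (default 1).
#' @param audio_noise_sd Microphone noise SD in full-scale units
#'   (default 0.002).
#' @param notify_jitter_max Maximum Bluetooth notification delay in s
#'   (default 0.2; must stay below the 0.5 s envelope search window).
#' @param dip_duration Turning-point dip duration in s (default 0.05; the
#'   rebound lasts twice as long).
#' @param dip_depth Fractional amplitude attenuation of the dip (default 0.5;
#'   the rebound overshoots by 0.8 times this).
#' @param amp_drift_per_daPa Multiplicative amplitude drift per daPa below
#'   +200 (default 5e-5, i.e. 3% across the 600 daPa sweep).
#' @param clock_offset_max Maximum |offset| of the pressure clock relative to
#'   the audio clock, in s (default 0.2).
#' @param seed Integer RNG seed; the same configs + seed reproduce a session
#'   exactly.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(pressure_noise_sd = 1, audio_noise_sd = 0.002,
                         notify_jitter_max = 0.2, dip_duration = 0.05,
                         dip_depth = 0.5, amp_drift_per_daPa = 5e-5,
                         clock_offset_max = 0.2, seed = 0L) {
  if (notify_jitter_max >= 0.5)
    validation_error("notify_jitter_max must stay below the 0.5 s search window")
  for (v in list(pressure_noise_sd, audio_noise_sd, notify_jitter_max,
                 dip_duration, dip_depth, amp_drift_per_daPa, clock_offset_max))
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      validation_error("noise_config values must be non-negative numbers")
  structure(list(pressure_noise_sd = pressure_noise_sd,
                 audio_noise_sd = audio_noise_sd,
                 notify_jitter_max = notify_jitter_max,
                 dip_duration = dip_duration, dip_depth = dip_depth,
                 amp_drift_per_daPa = amp_drift_per_daPa,
                 clock_offset_max = clock_offset_max,
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' @rdname noise_config
#' @param preset `"default"` or `"none"` (ideal, noise-free).
#' @export
noise_preset <- function(preset = c("default", "none"), seed = 0L) {
  preset <- match.arg(preset)
  if (preset == "default") return(noise_config(seed = seed))
  noise_config(pressure_noise_sd = 0, audio_noise_sd = 0, notify_jitter_max = 0,
               amp_drift_per_daPa = 0, clock_offset_max = 0, seed = seed)
}

#' Acoustic model configuration
#'
#' Maps the equivalent volume seen by the probe to the reflected 226 Hz tone
#' amplitude: `amplitude = amplitude_scale / (coupler_volume + V)`, optionally
#' times the drift term from [noise_config()]. Any strictly monotone
#' decreasing map would do (calibration inverts it); the reciprocal form
#' matches low-frequency rigid-cavity acoustics. `coupler_volume` is the
#' acoustic load of the probe head and tubing.
#'
#' @param amplitude_scale Numerator of the amplitude map (full-scale x mL).
#' @param coupler_volume Probe/tubing acoustic load in mL (default 7).
#' @param occluded_amplitude Reflected amplitude when the tip is blocked
#'   (default 0.5 full scale; the volume map does not apply to a blocked
#'   port).
#' @param out_of_ear_amplitude Reflected amplitude with the probe in open air.
#' @param tone_freq Probe-tone frequency in Hz (default 226).
#' @param level_reference dB SPL of a full-scale sinusoid (default 85).
#' @return A list of class `acoustic_config`.
#' @export
acoustic_config <- function(amplitude_scale = 0.476, coupler_volume = 7,
                            occluded_amplitude = 0.5,
                            out_of_ear_amplitude = 0.01,
                            tone_freq = 226, level_reference = 85) {
  structure(list(amplitude_scale = amplitude_scale,
                 coupler_volume = coupler_volume,
                 occluded_amplitude = occluded_amplitude,
                 out_of_ear_amplitude = out_of_ear_amplitude,
                 tone_freq = tone_freq, level_reference = level_reference),
            class = "acoustic_config")
}

#' Middle-ear model
#'
#' Parametric admittance-vs-pressure curve: a Gaussian peak of height `y_peak`
#' (compensated peak admittance) centred at the tympanometric peak pressure
#' `tpp`, with half-width `width`, on a flat baseline `v_ec` (ear canal
#' equivalent volume). Type B is flat (`y_peak = 0`). Defaults per type match
#' the clinical ranges: a normal Type A ear of 0.7 mL canal volume with a
#' 0.74 mL peak near +15 daPa; As shallow (< 0.3 mL), Ad deep (> 1.4 mL),
#' C peaked at -225 daPa, B flat with a large 2 mL canal volume.
#'
#' @param ear_type One of `"A"`, `"As"`, `"Ad"`, `"B"`, `"C"`, `"custom"`.
#' @param v_ec Ear canal equivalent volume in mL.
#' @param y_peak Compensated peak admittance in mL.
#' @param tpp Tympanometric peak pressure in daPa.
#' @param width Peak half-width in daPa (default 75).
#' @return A list of class `ear_model`.
#' @examples
#' ear_model("A")
#' ear_model("custom", v_ec = 1.1, y_peak = 0.5, tpp = -60, width = 90)
#' @export
ear_model <- function(ear_type = c("A", "As", "Ad", "B", "C", "custom"),
                      v_ec = NULL, y_peak = NULL, tpp = NULL, width = NULL) {
  ear_type <- match.arg(ear_type)
  defaults <- switch(ear_type,
    A  = list(v_ec = 0.7, y_peak = 0.74, tpp = 15,   width = 65),
    As = list(v_ec = 0.7, y_peak = 0.20, tpp = 10,   width = 65),
    Ad = list(v_ec = 0.7, y_peak = 1.80, tpp = 10,   width = 65),
    B  = list(v_ec = 2.0, y_peak = 0,    tpp = 0,    width = 65),
    C  = list(v_ec = 0.7, y_peak = 0.70, tpp = -225, width = 65),
    custom = list(v_ec = NULL, y_peak = NULL, tpp = NULL, width = 65))
  ear <- list(ear_type = ear_type,
              v_ec = v_ec %||% defaults$v_ec,
              y_peak = y_peak %||% defaults$y_peak,
              tpp = tpp %||% defaults$tpp,
              width = width %||% defaults$width)
  if (is.null(ear$v_ec) || is.null(ear$y_peak) || is.null(ear$tpp))
    validation_error("custom ear_model requires v_ec, y_peak and tpp")
  if (ear$v_ec <= 0) validation_error("v_ec must be positive")
  if (ear$y_peak < 0) validation_error("y_peak must be non-negative")
  if (ear$width <= 0) validation_error("width must be positive")
  if (ear$ear_type == "B" && ear$y_peak != 0)
    validation_error("Type B ears are flat: y_peak must be 0")
  structure(ear, class = "ear_model")
}

#' Admittance of an ear model at a given pressure
#'
#' Total equivalent volume seen by the probe:
#' `v_ec + y_peak * exp(-((p - tpp) / width)^2)`. Type B reduces to `v_ec` at
#' every pressure.
#'
#' @param ear An [ear_model()].
#' @param pressure Pressure(s) in daPa, within \[-400, 200\].
#' @return Equivalent volume(s) in mL.
#' @examples
#' admittance_at(ear_model("A"), 15) # v_ec + y_peak at the peak
#' @export
admittance_at <- function(ear, pressure) {
  stopifnot(inherits(ear, "ear_model"))
  if (any(pressure < -400 - 1e-9 | pressure > 200 + 1e-9))
    domain_error("pressure outside the measurement range [-400, 200] daPa")
  ear$v_ec + ear$y_peak * exp(-((pressure - ear$tpp) / ear$width)^2)
}

#' Gauge pressure produced by a plunger displacement
#'
#' Isothermal gas law for the sealed system: with total resting air volume
#' `V0 = coupled_volume + dead_volume` at ambient absolute pressure `Pa`,
#' advancing the plunger by `d` mm compresses the air to `V0 - area * d`,
#' giving gauge pressure `Pa * V0 / (V0 - area * d) - Pa` in daPa.
#'
#' @param d Plunger displacement in mm (positive = forward/compressing).
#' @param cfg A [pneumatic_config()].
#' @param coupled_volume Ear/cavity volume coupled to the probe, in mL.
#' @return Gauge pressure(s) in daPa.
#' @export
pressure_from_displacement <- function(d, cfg = pneumatic_config(),
                                       coupled_volume = 1) {
  if (coupled_volume <= 0) domain_error("coupled_volume must be positive")
  area <- syringe_area_ml_mm(cfg)
  v0 <- coupled_volume + cfg$dead_volume
  v <- v0 - area * d
  if (any(v <= 0))
    physical_limit_error("displacement would empty the system air volume")
  cfg$ambient_pressure * v0 / v - cfg$ambient_pressure
}

# Inverse: displacement producing gauge pressure p (sealed, mass m known).
displacement_for_pressure <- function(p, m, v0, area, pa) {
  (v0 - m / (pa + p)) / area
}

## ---- session builder ------------------------------------------------------

# Stateful sample-by-sample builder at the pressure-sensor rate. Tracks the
# trapped air mass (as P_abs * V) so sealed segments obey the gas law exactly
# and leaky segments relax the gauge pressure with time constant tau.
new_sim_builder <- function(pneu, coupled_volume) {
  e <- new.env(parent = emptyenv())
  e$dt <- 1 / pneu$sensor_rate
  e$pa <- pneu$ambient_pressure
  e$area <- syringe_area_ml_mm(pneu)
  e$v0 <- coupled_volume + pneu$dead_volume
  e$p <- 0; e$d <- 0
  e$m <- e$pa * e$v0
  e$ps <- list(); e$ds <- list(); e$modes <- list()
  e$n <- 0L
  e$marks <- list()
  e
}

b_time <- function(e) e$n * e$dt

b_mark <- function(e, name) { e$marks[[name]] <- b_time(e); invisible(e) }

b_append <- function(e, p, d, mode) {
  k <- length(e$ps) + 1L
  e$ps[[k]] <- p; e$ds[[k]] <- d
  e$modes[[k]] <- rep(mode, length(p))
  e$n <- e$n + length(p)
  e$p <- p[length(p)]; e$d <- d[length(d)]
  invisible(e)
}

# Hold everything still (sealed) for dur seconds.
b_hold <- function(e, dur, mode) {
  n <- max(1L, round(dur / e$dt))
  b_append(e, rep(e$p, n), rep(e$d, n), mode)
}

# Pressure enters/leaves through the ear tip at constant plunger position
# (probe insertion): gauge ramps linearly to p_target, mass re-equilibrates.
b_insertion <- function(e, p_target, dur, mode) {
  n <- max(1L, round(dur / e$dt))
  p <- e$p + (seq_len(n) / n) * (p_target - e$p)
  d <- rep(e$d, n)
  b_append(e, p, d, mode)
  e$m <- (e$pa + e$p) * (e$v0 - e$area * e$d)
  invisible(e)
}

# Sealed pressure-feedback ramp: gauge follows a linear trajectory to
# p_target at |rate| daPa/s; plunger position derived from the gas law.
b_pressure_ramp <- function(e, p_target, rate, mode) {
  span <- p_target - e$p
  n <- max(1L, round(abs(span) / rate / e$dt))
  p <- e$p + (seq_len(n) / n) * span
  d <- displacement_for_pressure(p, e$m, e$v0, e$area, e$pa)
  b_append(e, p, d, mode)
}

# Motor-rate-controlled segment with optional leak; integrates the split-step
# gas-law + leak update. stop_fn(p, d) ends the segment early.
b_motor <- function(e, d_rate, dur, tau, mode, stop_fn = NULL) {
  n <- max(1L, round(dur / e$dt))
  p <- numeric(n); d <- numeric(n)
  pk <- e$p; dk <- e$d; mk <- e$m
  decay <- if (is.finite(tau)) exp(-e$dt / tau) else 1
  used <- n
  for (i in seq_len(n)) {
    dk <- dk + d_rate * e$dt
    v <- e$v0 - e$area * dk
    if (v <= 0) physical_limit_error("plunger emptied the system air volume")
    pk <- (mk / v - e$pa) * decay
    mk <- (e$pa + pk) * v
    p[i] <- pk; d[i] <- dk
    if (!is.null(stop_fn) && stop_fn(pk, dk)) { used <- i; break }
  }
  b_append(e, p[seq_len(used)], d[seq_len(used)], mode)
  e$m <- mk
  invisible(e)
}

# Leak-only decay at frozen plunger position.
b_decay <- function(e, tau, dur, mode) {
  n <- max(1L, round(dur / e$dt))
  p <- e$p * exp(-(seq_len(n)) * e$dt / tau)
  d <- rep(e$d, n)
  b_append(e, p, d, mode)
  e$m <- (e$pa + e$p) * (e$v0 - e$area * e$d)
  invisible(e)
}

## ---- scenario assembly ----------------------------------------------------

# Turn a finished builder into a tymp_session, adding acoustics and noise.
# v_equiv_fn(p) maps clamped pressure to equivalent volume for "ear" samples.
finish_session <- function(e, pneu, noise, acoustic, v_equiv_fn,
                           events, truth, dip_at = numeric(0)) {
  n <- e$n
  t_p <- (seq_len(n) - 1L) * e$dt
  p_clean <- unlist(e$ps, use.names = FALSE)
  d_all <- unlist(e$ds, use.names = FALSE)
  modes <- unlist(e$modes, use.names = FALSE)

  amp_p <- rep(acoustic$out_of_ear_amplitude, n)
  ear_idx <- modes == "ear"
  if (any(ear_idx)) {
    pcl <- pmin(pmax(p_clean[ear_idx], -400), 200)
    base <- acoustic$amplitude_scale /
      (acoustic$coupler_volume + v_equiv_fn(pcl))
    amp_p[ear_idx] <- base * (1 + noise$amp_drift_per_daPa * (200 - pcl))
  }
  amp_p[modes == "occluded"] <- acoustic$occluded_amplitude

  fs <- 24000
  n_a <- round(n * e$dt * fs)
  t_a <- (seq_len(n_a) - 1L) / fs
  amp_a <- stats::approx(t_p, amp_p, t_a, rule = 2)$y
  # Motor-reversal transient: a smooth dip just before the reversal and a
  # rebound overshoot whose crest sits at the reversal instant. Hann pulses
  # keep the modulation inside the 220-230 Hz analysis band.
  for (tm in dip_at) {
    rel <- t_a - tm
    g <- 1 -
      noise$dip_depth * hann_pulse(rel, -0.06, noise$dip_duration) +
      0.8 * noise$dip_depth * hann_pulse(rel, -0.01, 2 * noise$dip_duration)
    amp_a <- amp_a * g
  }
  audio_samples <- amp_a * sin(2 * pi * acoustic$tone_freq * t_a)
  if (noise$audio_noise_sd > 0)
    audio_samples <- audio_samples + stats::rnorm(n_a, 0, noise$audio_noise_sd)

  offset <- if (noise$clock_offset_max > 0)
    stats::runif(1, -noise$clock_offset_max, noise$clock_offset_max) else 0
  p_out <- p_clean
  if (noise$pressure_noise_sd > 0)
    p_out <- p_out + stats::rnorm(n, 0, noise$pressure_noise_sd)
  p_out <- pmin(pmax(p_out, -1000), 1000)

  truth$clock_offset <- offset
  motor <- tibble::tibble(time_s = t_p + offset, displacement_mm = d_all)
  tymp_session(
    audio = audio_trace(audio_samples, fs, acoustic$level_reference),
    pressure = pressure_trace(tibble::tibble(time_s = t_p + offset,
                                             pressure_daPa = p_out)),
    events = events, motor = motor, truth = truth)
}

true_tympanogram <- function(v_equiv_fn) {
  grid <- tymp_grid()
  tympanogram(tibble::tibble(pressure_daPa = grid,
                             admittance_mL = v_equiv_fn(grid)))
}

# Shared preamble: baseline out of ear, insertion spike, settle, one forward
# seal-probe step, occlusion-check hold. Returns the builder with marks.
build_preamble <- function(e, pneu, occluded = FALSE) {
  mode_in <- if (occluded) "occluded" else "ear"
  b_hold(e, 0.5, "out")
  b_mark(e, "insertion")
  b_insertion(e, 40, 0.1, mode_in)
  b_hold(e, 0.4, mode_in)
  b_mark(e, "probe_start")
  b_motor(e, pneu$step_size / pneu$step_duration, pneu$step_duration,
          Inf, mode_in)
  b_mark(e, "probe_end")
  b_hold(e, 0.3, mode_in)
  b_mark(e, "occl_end")
  invisible(e)
}

sim_seed <- function(noise) noise$seed

#' Simulate a complete sealed measurement session
#'
#' Runs the full scripted protocol against an [ear_model()]: probe-out
#' baseline, insertion spike, one 0.5 mm seal-probe step, occlusion-check
#' hold, fast pressurization to +200 daPa, slow sweep to -400 daPa, fast
#' return to ambient. The reflected 226 Hz tone amplitude follows
#' `admittance_at(ear, p(t))` through the acoustic map, with brief dips at
#' both sweep turning points and jittered sweep-boundary notifications.
#'
#' @param ear An [ear_model()].
#' @param pneu A [pneumatic_config()].
#' @param noise A [noise_config()].
#' @param acoustic An [acoustic_config()].
#' @return A [tymp_session()] whose `truth` element carries the true turning
#'   times `t3`/`t5`, sweep duration, the true tympanogram on the canonical
#'   grid, and the generating parameters.
#' @examples
#' s <- simulate_session(ear_model("A"), noise = noise_preset("none"))
#' s$truth$sweep_duration
#' @export
simulate_session <- function(ear = ear_model("A"), pneu = pneumatic_config(),
                             noise = noise_config(),
                             acoustic = acoustic_config()) {
  withr::with_seed(sim_seed(noise), {
    v_fn <- function(p) admittance_at(ear, p)
    e <- new_sim_builder(pneu, coupled_volume = ear$v_ec)
    build_preamble(e, pneu)
    b_pressure_ramp(e, 200, pneu$fast_speed, "ear")
    b_mark(e, "t3")
    b_pressure_ramp(e, -400, pneu$sweep_speed, "ear")
    b_mark(e, "t5")
    b_pressure_ramp(e, 0, pneu$fast_speed, "ear")
    b_hold(e, 0.3, "ear")
    t3 <- e$marks$t3; t5 <- e$marks$t5
    jit <- stats::runif(2, 0, noise$notify_jitter_max)
    events <- session_events(
      seal_found_t = e$marks$probe_end,
      sweep_start_notify_t = t3 + jit[1],
      sweep_end_notify_t = t5 + jit[2])
    truth <- list(scenario = "sealed", ear_type = ear$ear_type,
                  t3 = t3, t5 = t5, sweep_duration = t5 - t3,
                  notify_jitter = jit,
                  probe_window = c(e$marks$probe_start, e$marks$probe_end),
                  metrics_true = list(v_ec = ear$v_ec, y_peak = ear$y_peak,
                                      tpp = ear$tpp, width = ear$width),
                  tympanogram_true = true_tympanogram(v_fn))
    finish_session(e, pneu, noise, acoustic, v_fn, events, truth,
                   dip_at = c(t3, t5))
  })
}

#' Simulate a calibration-cavity session
#'
#' Identical protocol to [simulate_session()] over a rigid hard-backed cavity
#' whose admittance is constant and equal to its volume.
#'
#' @param volume Cavity volume in mL, within \[0, 5\] (0 = probe dead volume
#'   only).
#' @inheritParams simulate_session
#' @return A [tymp_session()].
#' @export
simulate_cavity <- function(volume, pneu = pneumatic_config(),
                            noise = noise_config(),
                            acoustic = acoustic_config()) {
  if (!is_number(volume) || volume < 0)
    domain_error("cavity volume must be a non-negative number")
  if (volume > 5) domain_error("cavity volume must not exceed 5 mL")
  withr::with_seed(sim_seed(noise), {
    v_fn <- function(p) rep(volume, length(p))
    e <- new_sim_builder(pneu, coupled_volume = max(volume, 1e-6))
    build_preamble(e, pneu)
    b_pressure_ramp(e, 200, pneu$fast_speed, "ear")
    b_mark(e, "t3")
    b_pressure_ramp(e, -400, pneu$sweep_speed, "ear")
    b_mark(e, "t5")
    b_pressure_ramp(e, 0, pneu$fast_speed, "ear")
    b_hold(e, 0.3, "ear")
    t3 <- e$marks$t3; t5 <- e$marks$t5
    jit <- stats::runif(2, 0, noise$notify_jitter_max)
    events <- session_events(
      seal_found_t = e$marks$probe_end,
      sweep_start_notify_t = t3 + jit[1],
      sweep_end_notify_t = t5 + jit[2])
    truth <- list(scenario = "cavity", cavity_volume = volume,
                  t3 = t3, t5 = t5, sweep_duration = t5 - t3,
                  notify_jitter = jit,
                  probe_window = c(e$marks$probe_start, e$marks$probe_end),
                  tympanogram_true = true_tympanogram(v_fn))
    finish_session(e, pneu, noise, acoustic, v_fn, events, truth,
                   dip_at = c(t3, t5))
  })
}

#' Simulate an unsealed (no-seal) probing session
#'
#' The probe sits outside the ear: each 0.5 mm forward step leaks away with
#' time constant `leak_time_constant` (default tuned so the observed step
#' rate is about 2 daPa/s), the plunger backs off, and the cycle repeats.
#'
#' @param n_steps Number of forward/backward probe cycles (default 5).
#' @param leak_time_constant Leak time constant in s.
#' @inheritParams simulate_session
#' @return A [tymp_session()]; `truth$probe_windows` lists the forward-step
#'   windows on the pressure clock.
#' @export
simulate_no_seal <- function(pneu = pneumatic_config(), noise = noise_config(),
                             acoustic = acoustic_config(), n_steps = 5,
                             leak_time_constant = NO_SEAL_LEAK_TAU) {
  withr::with_seed(sim_seed(noise), {
    e <- new_sim_builder(pneu, coupled_volume = 1)
    b_hold(e, 0.5, "out")
    rate <- pneu$step_size / pneu$step_duration
    windows <- vector("list", n_steps)
    for (k in seq_len(n_steps)) {
      t0 <- b_time(e)
      b_motor(e, rate, pneu$step_duration, leak_time_constant, "out")
      windows[[k]] <- c(t0, b_time(e))
      b_motor(e, -rate, pneu$step_duration, leak_time_constant, "out")
    }
    b_hold(e, 0.5, "out")
    events <- session_events()
    truth <- list(scenario = "no_seal",
                  probe_window = windows[[1]], probe_windows = windows,
                  leak_time_constant = leak_time_constant)
    finish_session(e, pneu, noise, acoustic, function(p) rep(1, length(p)),
                   events, truth)
  })
}

#' Simulate an occluded-tip session
#'
#' Pressure behaves as sealed (the blocked port still traps air) but the
#' reflected tone is near-total, far above the 65 dB SPL occlusion threshold.
#' The protocol stops after the occlusion check, as the device would.
#'
#' @inheritParams simulate_session
#' @return A [tymp_session()] with `events$occluded = TRUE`.
#' @export
simulate_occluded <- function(pneu = pneumatic_config(), noise = noise_config(),
                              acoustic = acoustic_config()) {
  withr::with_seed(sim_seed(noise), {
    e <- new_sim_builder(pneu, coupled_volume = 0.05)
    build_preamble(e, pneu, occluded = TRUE)
    b_decay(e, 0.1, 0.4, "occluded")
    b_hold(e, 0.3, "occluded")
    events <- session_events(seal_found_t = e$marks$probe_end, occluded = TRUE)
    truth <- list(scenario = "occluded",
                  probe_window = c(e$marks$probe_start, e$marks$probe_end))
    finish_session(e, pneu, noise, acoustic,
                   function(p) rep(0.05, length(p)), events, truth)
  })
}

#' Simulate a session that loses its seal mid-sweep
#'
#' The sweep proceeds normally until `loss_after` seconds past the sweep
#' start, when the probe dislodges: pressure collapses to ambient with a fast
#' leak and the reflected tone drops to the out-of-ear level.
#'
#' @param loss_after Seconds into the sweep at which the seal is lost
#'   (default 2.5).
#' @inheritParams simulate_session
#' @return A [tymp_session()] with `events$seal_lost_t` set.
#' @export
simulate_seal_loss <- function(ear = ear_model("A"), pneu = pneumatic_config(),
                               noise = noise_config(),
                               acoustic = acoustic_config(), loss_after = 2.5) {
  withr::with_seed(sim_seed(noise), {
    v_fn <- function(p) admittance_at(ear, p)
    e <- new_sim_builder(pneu, coupled_volume = ear$v_ec)
    build_preamble(e, pneu)
    b_pressure_ramp(e, 200, pneu$fast_speed, "ear")
    b_mark(e, "t3")
    t3 <- e$marks$t3
    p_at_loss <- 200 - pneu$sweep_speed * loss_after
    if (p_at_loss <= -400)
      domain_error("loss_after places the loss beyond the sweep end")
    b_pressure_ramp(e, p_at_loss, pneu$sweep_speed, "ear")
    b_mark(e, "seal_lost")
    b_decay(e, 0.05, 0.6, "out")
    b_hold(e, 0.8, "out")
    jit <- stats::runif(1, 0, noise$notify_jitter_max)
    events <- session_events(
      seal_found_t = e$marks$probe_end,
      sweep_start_notify_t = t3 + jit,
      seal_lost_t = e$marks$seal_lost)
    truth <- list(scenario = "seal_loss", t3 = t3,
                  seal_lost_t = e$marks$seal_lost,
                  probe_window = c(e$marks$probe_start, e$marks$probe_end))
    finish_session(e, pneu, noise, acoustic, v_fn, events, truth,
                   dip_at = t3)
  })
}

#' Simulate a session that triggers the 16 mm safety abort
#'
#' A partial leak opens at pressurization: the seal probe still passes the
#' 17 daPa/s check, but the leak bleeds air as fast as the advancing plunger
#' supplies it, pressure stalls below +200 daPa, and the plunger runs forward
#' until it crosses the `max_forward_travel` safety limit.
#'
#' @param leak_time_constant Partial-leak time constant in s (default 0.6,
#'   which stalls the pressurization below target).
#' @inheritParams simulate_session
#' @return A [tymp_session()] with `events$aborted = TRUE`.
#' @export
simulate_abort <- function(ear = ear_model("A"), pneu = pneumatic_config(),
                           noise = noise_config(),
                           acoustic = acoustic_config(),
                           leak_time_constant = 0.6) {
  withr::with_seed(sim_seed(noise), {
    v_fn <- function(p) admittance_at(ear, p)
    e <- new_sim_builder(pneu, coupled_volume = ear$v_ec)
    build_preamble(e, pneu)
    gain <- e$pa * e$area / e$v0              # daPa per mm, small-signal
    d_rate <- pneu$fast_speed / gain
    limit <- pneu$max_forward_travel + 2 * pneu$step_size
    b_motor(e, d_rate, 30, leak_time_constant, "ear",
            stop_fn = function(p, d) d > limit)
    b_mark(e, "aborted")
    b_decay(e, 0.2, 0.5, "ear")
    b_hold(e, 0.3, "out")
    events <- session_events(seal_found_t = e$marks$probe_end, aborted = TRUE)
    truth <- list(scenario = "abort", aborted_t = e$marks$aborted,
                  probe_window = c(e$marks$probe_start, e$marks$probe_end),
                  leak_time_constant = leak_time_constant)
    finish_session(e, pneu, noise, acoustic, v_fn, events, truth)
  })
}
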
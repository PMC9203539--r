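test_that("envelope is flat for a stationary tone and rejects out-of-band energy", {
  fs <- 24000
  t <- (0:(2 * fs)) / fs
  tone <- audio_trace(0.1 * sin(2 * pi * 226 * t), fs)
  e <- compute_envelope(tone)
  mid <- e$level[e$frame_time > 0.3 & e$frame_time < 1.7]
  expect_lt(stats::sd(mid) / mean(mid), 0.01)
  expect_equal(mean(mid) * sqrt(2), 0.1, tolerance = 0.01)

  far <- audio_trace(0.1 * sin(2 * pi * 1000 * t), fs)
  ef <- compute_envelope(far)
  expect_lt(max(ef$level[ef$frame_time > 0.3 & ef$frame_time < 1.7]), 1e-4)

  expect_tymp_error(compute_envelope(tone, band = c(220, 13000)),
                    "tymp_domain_error")
})

test_that("envelope tracks slow amplitude modulation within one frame", {
  fs <- 24000
  t <- (0:(3 * fs)) / fs
  amp <- 0.05 * (1 + 0.5 * sin(2 * pi * 1.5 * t))
  a <- audio_trace(amp * sin(2 * pi * 226 * t), fs)
  e <- compute_envelope(a)
  sel <- e$frame_time > 0.4 & e$frame_time < 2.6
  analytic <- 0.05 * (1 + 0.5 * sin(2 * pi * 1.5 * e$frame_time[sel]))
  err <- abs(e$level[sel] * sqrt(2) - analytic)
  # bounded by the modulation change across one frame plus filter droop
  frame <- attr(e, "frame_length")
  slope_max <- max(abs(diff(analytic))) / diff(e$frame_time[sel])[1] * frame
  expect_lt(max(err), slope_max + 0.05 * max(analytic))
})

test_that("boundary refinement recovers the turning instants within one frame", {
  s0 <- zero_session_A()
  e0 <- compute_envelope(s0$audio)
  frame <- attr(e0, "frame_length")
  t3 <- refine_boundary(e0, s0$events$sweep_start_notify_t, "max_pressure")
  t5 <- refine_boundary(e0, s0$events$sweep_end_notify_t, "min_pressure")
  expect_lt(abs(t3 - s0$truth$t3), frame + 1e-9)
  expect_lt(abs(t5 - s0$truth$t5), frame + 1e-9)

  sj <- simulate_session(ear_model("A"),
                         noise = noise_config(notify_jitter_max = 0.2, seed = 4))
  ej <- compute_envelope(sj$audio)
  t3j <- refine_boundary(ej, sj$events$sweep_start_notify_t, "max_pressure")
  expect_lt(abs(t3j - sj$truth$t3), frame + 1e-9)

  # flat envelope: no dip, falls back to the notification with a warning
  fs <- 24000
  flat <- audio_trace(0.1 * sin(2 * pi * 226 * (0:(2 * fs)) / fs), fs)
  ef <- compute_envelope(flat)
  expect_warning(out <- refine_boundary(ef, 1.5, "max_pressure"),
                 class = "tymp_sync_warning")
  expect_equal(out, 1.5)
})

test_that("synchronize aligns the clocks and counts the sweep samples", {
  s0 <- zero_session_A()
  sy0 <- synchronize(s0$audio, s0$pressure, s0$events)
  dt <- 1 / pneumatic_config()$sensor_rate
  # zero noise, zero offset: the remap is the identity within one sample
  expect_lt(abs(sy0$remap["slope"] - 1), 0.01)
  expect_lt(abs(sy0$remap["intercept"]), dt)
  expect_gte(sy0$n_sweep_samples, 10)

  # affine remap preserves ordering and count
  expect_equal(nrow(sy0$pressure), nrow(s0$pressure))
  expect_true(all(diff(sy0$pressure$time_s) > 0))

  # both notifications pointing at the same turning dip: the refined
  # boundaries collapse out of order and synchronization must fail
  ev_bad <- session_events(
    sweep_start_notify_t = s0$events$sweep_start_notify_t + 0.1,
    sweep_end_notify_t = s0$events$sweep_start_notify_t + 0.2)
  expect_tymp_error(suppressWarnings(
    synchronize(s0$audio, s0$pressure, ev_bad)), "tymp_sync_error")
  ev_none <- session_events()
  expect_tymp_error(synchronize(s0$audio, s0$pressure, ev_none), "tymp_sync_error")
})

test_that("sweep boundaries are recovered within one frame across a 50-seed jittered battery", {
  frame <- 212 / 24000
  worst <- 0
  for (seed in 0:49) {
    s <- simulate_session(ear_model("A"),
                          noise = noise_config(notify_jitter_max = 0.4,
                                               seed = seed))
    sy <- suppressWarnings(synchronize(s$audio, s$pressure, s$events))
    worst <- max(worst, abs(sy$t3 - s$truth$t3), abs(sy$t5 - s$truth$t5))
  }
  expect_lt(worst, frame + 1e-9)
})
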
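test_that("single-bin magnitude of an on-bin sinusoid equals N*A/2", {
  for (A in c(0.05, 0.3, 0.9)) {
    x <- A * sin(2 * pi * 226 * (0:23999) / 24000)
    expect_equal(tone_bin_magnitude(x), 24000 * A / 2, tolerance = 1e-9)
  }
  # noise-only segment stays far below the tone
  withr::with_seed(3, {
    noise_mag <- tone_bin_magnitude(stats::rnorm(531, 0, 0.002))
    tone_mag <- tone_bin_magnitude(0.05 * sin(2 * pi * 226 * (0:530) / 24000))
    expect_lt(noise_mag, tone_mag / 20)
  })
})

test_that("raw curve is maximal far from the peak and minimal at the peak", {
  s <- zero_session_A()
  sy <- synchronize(s$audio, s$pressure, s$events)
  raw <- extract_raw_curve(sy, s$audio)
  expect_gte(nrow(raw), 10)
  p_at_min <- raw$pressure_daPa[which.min(raw$amplitude)]
  expect_lt(abs(p_at_min - 15), 30)  # amplitude dips at the admittance peak
  far <- abs(raw$pressure_daPa - 15) > 250
  near <- abs(raw$pressure_daPa - 15) < 30
  expect_gt(min(raw$amplitude[far]), max(raw$amplitude[near]))
})

test_that("identity calibration passes amplitudes through unchanged", {
  curve <- data.frame(pressure_daPa = seq(-400, 200, 40),
                      amplitude = seq(1, 3, length.out = 16))
  out <- apply_calibration(curve, calibration_model(0, 0, 1, 0))
  expect_equal(out$admittance_mL, curve$amplitude)
  # tilted flat input becomes flat after compensation
  grid <- tymp_grid()
  m <- 4e-4
  tilted <- data.frame(pressure_daPa = grid,
                       amplitude = 2 + m * (grid + 400))
  cal <- calibration_model(0, 0, 1, 0, m = m, b = 2)
  flat <- apply_calibration(tilted, cal)
  expect_lt(max(abs(flat$admittance_mL)), 1e-6)
})

test_that("zero-noise cavity analyses come out flat at the true volume", {
  res <- suppressWarnings(analyze_session(zero_cavities()[[4]], zero_cal()))
  expect_lt(max(abs(res$tympanogram$admittance_mL - 3)), 0.02 + 0.01)
  expect_true(res$metrics$is_flat)
})

test_that("smoothing preserves constants, fills gaps, and keeps the 121-bin grid", {
  grid <- tymp_grid()
  const <- data.frame(pressure_daPa = grid, admittance_mL = rep(1, 121))
  sm <- smooth_tympanogram(const)
  expect_equal(nrow(sm), 121)
  expect_equal(sm$pressure_daPa, grid)
  expect_equal(sm$admittance_mL, rep(1, 121))

  # empty interior bin between 0.8 and 1.0 neighbourhoods fills to their mean
  k <- 60
  vals <- ifelse(seq_along(grid) < k, 0.8, 1.0)
  gap <- data.frame(pressure_daPa = grid[-k], admittance_mL = vals[-k])
  smg <- smooth_tympanogram(gap)
  expect_equal(smg$admittance_mL[k], 0.9)

  # smoothing never widens the value range
  withr::with_seed(21, {
    for (i in 1:10) {
      y <- runif(121, 0.2, 2)
      r <- smooth_tympanogram(data.frame(pressure_daPa = grid,
                                         admittance_mL = y))
      expect_gte(min(r$admittance_mL), min(y) - 1e-12)
      expect_lte(max(r$admittance_mL), max(y) + 1e-12)
    }
  })
  expect_tymp_error(
    smooth_tympanogram(data.frame(pressure_daPa = 500 + 1:20,
                                  admittance_mL = 1)),
    "tymp_insufficient_data_error")
})

test_that("metrics: baseline compensation, peak location, flatness, tie-break", {
  grid <- tymp_grid()
  flat <- tympanogram(data.frame(pressure_daPa = grid, admittance_mL = 2))
  m <- compute_metrics(flat)
  expect_equal(m$ear_canal_volume, 2)
  expect_equal(m$peak_admittance, 0)
  expect_true(m$is_flat)

  # equal maxima at -20 and +10: tie broken towards 0 daPa
  y <- rep(1, 121)
  y[grid == -20] <- 1.5; y[grid == 10] <- 1.5
  tt <- tympanogram(data.frame(pressure_daPa = grid, admittance_mL = y))
  expect_equal(compute_metrics(tt)$peak_pressure, 10)

  s <- zero_session_A()
  res <- analyze_session(s, zero_cal())
  mm <- res$metrics
  expect_lt(abs(mm$ear_canal_volume - 0.7), 0.05)
  expect_lt(abs(mm$peak_admittance - 0.74), 0.05)
  expect_lte(abs(mm$peak_pressure - 15), 5)

  # perforation-like ear: flat with a large canal volume
  sb <- simulate_session(ear_model("B", v_ec = 2.5),
                         noise = noise_config(seed = 6))
  mb <- analyze_session(sb, zero_cal())$metrics
  expect_true(mb$is_flat)
  expect_gt(mb$ear_canal_volume, 1.5)
})

test_that("tidy and autoplot work on analysis results", {
  res <- analyze_session(zero_session_A(), zero_cal())
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("peak_admittance", "peak_pressure", "ear_canal_volume",
                     "is_flat", "peak_admittance_absolute"))
  p <- autoplot(res$tympanogram)
  expect_s3_class(p, "ggplot")
  p2 <- plot_tympanogram(res$tympanogram, res$metrics)
  expect_s3_class(p2, "ggplot")
})
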
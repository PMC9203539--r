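test_that("session files parse to validated traces and round-trip bit-exactly", {
  dir <- withr::local_tempdir()
  # 1 s of silence at 24 kHz plus a 10-row pressure record
  write_wav_pcm16(rep(0, 24000), file.path(dir, "audio.wav"), 24000)
  utils::write.csv(data.frame(time_s = 0:9 / 10, pressure_daPa = rep(0, 10)),
                   file.path(dir, "pressure.csv"), row.names = FALSE)
  jsonlite::write_json(list(seal_found_t = 1, sweep_start_notify_t = 2,
                            sweep_end_notify_t = 6, seal_lost_t = NULL,
                            aborted = FALSE, occluded = FALSE),
                       file.path(dir, "events.json"), auto_unbox = TRUE,
                       null = "null")
  s <- read_session(dir)
  expect_length(s$audio$samples, 24000)
  expect_equal(s$audio$sample_rate, 24000)
  expect_equal(nrow(s$pressure), 10)
  expect_true(is.na(s$events$seal_lost_t))

  # full simulated session round-trip; PCM16 quantization is the identity on
  # already-quantized samples
  sim <- simulate_session(ear_model("A"), noise = noise_config(seed = 3))
  d2 <- file.path(dir, "roundtrip")
  write_session(sim, d2)
  back <- read_session(d2)
  q <- pmin(pmax(sim$audio$samples, -1), 32767 / 32768)
  q <- pmin(pmax(as.integer(round(q * 32768)), -32768L), 32767L) / 32768
  expect_identical(back$audio$samples, q)
  rt <- tempfile(fileext = ".wav")
  write_wav_pcm16(back$audio$samples, rt, 24000)
  expect_identical(read_wav_pcm16(rt)$samples, back$audio$samples)
  expect_equal(back$pressure$pressure_daPa, sim$pressure$pressure_daPa)
  expect_equal(unclass(back$events), unclass(sim$events))
  expect_false(is.null(back$motor))
})

test_that("readers reject invalid inputs with named condition classes", {
  expect_tymp_error(
    pressure_trace(data.frame(time_s = c(0, 0), pressure_daPa = c(1, 2))),
    "tymp_validation_error")
  expect_tymp_error(
    pressure_trace(data.frame(time_s = 0:1, pressure_daPa = c(0, 2000))),
    "tymp_validation_error")
  expect_tymp_error(audio_trace(numeric(0)), "tymp_validation_error")
  expect_tymp_error(audio_trace(c(0, NA)), "tymp_validation_error")
  expect_tymp_error(
    session_events(sweep_start_notify_t = 5, sweep_end_notify_t = 2),
    "tymp_validation_error")
  dir <- withr::local_tempdir()
  writeLines("not a wav", file.path(dir, "bad.wav"))
  expect_tymp_error(read_wav_pcm16(file.path(dir, "bad.wav")),
                    "tymp_format_error")
})

test_that("tympanogram CSV has one row per 5 daPa grid point and round-trips", {
  grid <- seq(-400, 200, by = 5)
  # grid cardinality oracle: brute-force enumeration of the bin edges
  expect_equal(length(grid), sum(!is.na(match(seq(-400, 200), grid))))
  flat <- tympanogram(data.frame(pressure_daPa = grid, admittance_mL = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  m <- compute_metrics(flat)
  write_tympanogram(flat, path, metrics = m)
  expect_equal(nrow(utils::read.csv(path)), 121)
  back <- read_tympanogram(path)
  expect_lt(max(abs(back$admittance_mL - flat$admittance_mL)), 1e-9)
  expect_true(file.exists(sub("\\.csv$", "_metrics.json", path)))

  expect_tymp_error(
    tympanogram(data.frame(pressure_daPa = numeric(0),
                           admittance_mL = numeric(0))),
    "tymp_validation_error")
  expect_tymp_error(
    tympanogram(data.frame(pressure_daPa = c(-400, -390),
                           admittance_mL = c(1, 1))),
    "tymp_validation_error")
})

test_that("calibration JSON round-trips losslessly and validates its schema", {
  cal <- calibration_model(0, 0, 1, 0, m = 0.001, b = -0.05,
                           gain_setting = 85)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  for (k in c("p1", "p2", "p3", "p4", "m", "b", "gain_setting"))
    expect_identical(back[[k]], cal[[k]])

  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$mystery <- "?"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_warning(read_calibration(path), class = "tymp_schema_warning")

  obj$mystery <- NULL; obj$p2 <- "abc"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_tymp_error(read_calibration(path), "tymp_schema_error")

  obj$p2 <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_tymp_error(read_calibration(path), "tymp_schema_error")
})
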
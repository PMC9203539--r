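test_that("admittance model reproduces the intended curve shapes", {
  b <- ear_model("B", v_ec = 2.0)
  expect_equal(admittance_at(b, seq(-400, 200, by = 50)),
               rep(2.0, 13))
  a <- ear_model("custom", v_ec = 0.7, y_peak = 0.74, tpp = 15)
  expect_equal(admittance_at(a, 15), 0.7 + 0.74)
  cc <- ear_model("C", tpp = -225)
  grid <- tymp_grid()
  expect_equal(grid[which.max(admittance_at(cc, grid))], -225)
  expect_tymp_error(admittance_at(a, 300), "tymp_domain_error")
  expect_tymp_error(ear_model("B", y_peak = 0.3), "tymp_validation_error")
})

test_that("gas-law pressure matches an independent bisection oracle to 1e-9", {
  cfg0 <- pneumatic_config()
  expect_equal(pressure_from_displacement(0, cfg0, 1), 0)
  expect_gt(pressure_from_displacement(0.5, cfg0, 1), 0)
  expect_lt(pressure_from_displacement(-0.5, cfg0, 1), 0)

  withr::with_seed(42, {
    for (i in 1:100) {
      cfg <- pneumatic_config(syringe_diameter = runif(1, 8, 16),
                              dead_volume = runif(1, 4, 14))
      cv <- runif(1, 0.3, 5); d <- runif(1, -3, 3)
      p <- pressure_from_displacement(d, cfg, cv)
      # oracle: bisection on (Pa + p) * (V0 - A d) = Pa * V0
      a <- pi * (cfg$syringe_diameter / 2)^2 / 1000
      v0 <- cv + cfg$dead_volume
      f <- function(pp) (cfg$ambient_pressure + pp) * (v0 - a * d) -
        cfg$ambient_pressure * v0
      lo <- -5000; hi <- 5000
      for (k in 1:200) {
        mid <- (lo + hi) / 2
        if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
      }
      expect_lt(abs(p - (lo + hi) / 2), 1e-9 * max(1, abs(p)))
    }
  })
  expect_tymp_error(pressure_from_displacement(200, cfg0, 1),
                    "tymp_physical_limit_error")
})

test_that("sessions are exactly reproducible from configs and seed", {
  a <- simulate_session(ear_model("A"), noise = noise_config(seed = 11))
  b <- simulate_session(ear_model("A"), noise = noise_config(seed = 11))
  expect_identical(a$audio$samples, b$audio$samples)
  expect_identical(a$pressure$pressure_daPa, b$pressure$pressure_daPa)
  expect_identical(unclass(a$events), unclass(b$events))
  c <- simulate_session(ear_model("A"), noise = noise_config(seed = 12))
  expect_false(identical(a$audio$samples, c$audio$samples))
})

test_that("sweep duration equals the span over the sweep speed", {
  s <- zero_session_A()
  pneu <- pneumatic_config()
  nominal <- (200 - (-400)) / pneu$sweep_speed
  expect_lt(abs(s$truth$sweep_duration - nominal), 1 / pneu$sensor_rate)
  # cross-check against the trace's own turning instants
  tr <- s$pressure
  measured <- tr$time_s[which.min(tr$pressure_daPa)] -
    tr$time_s[which.max(tr$pressure_daPa)]
  expect_lt(abs(measured - nominal), 2 / pneu$sensor_rate)
})

test_that("ground-truth tympanogram is the admittance model on the grid", {
  s <- zero_session_A()
  grid <- tymp_grid()
  expect_identical(s$truth$tympanogram_true$admittance_mL,
                   admittance_at(ear_model("A"), grid))
})

test_that("reflected tone amplitude decreases strictly with cavity volume", {
  ac <- acoustic_config()
  v <- seq(0, 5, by = 0.25)
  amp <- ac$amplitude_scale / (ac$coupler_volume + v)
  expect_true(all(diff(amp) < 0))
  means <- vapply(zero_cavities(), function(s) {
    t <- s$truth$t3 + 1
    i <- floor(t * 24000) + seq_len(24000)
    sqrt(mean(s$audio$samples[i]^2))
  }, numeric(1))
  expect_true(all(diff(means) < 0))   # 0 mL loudest, 5 mL quietest
  expect_tymp_error(simulate_cavity(-1), "tymp_domain_error")
})

test_that("no-seal, sealed and occluded sessions show the documented signatures", {
  ns <- simulate_no_seal(noise = noise_preset("none"))
  r_ns <- step_rate(ns$pressure, ns$truth$probe_window)
  expect_gt(r_ns, 1); expect_lt(r_ns, 5)        # ~2 daPa/s out of the ear

  sealed <- zero_session_A()
  r_s <- step_rate(sealed$pressure, sealed$truth$probe_window)
  expect_gt(r_s, 17)                            # exceeds the seal threshold

  occ <- simulate_occluded(noise = noise_preset("none"))
  w <- occ$truth$probe_window
  lev <- attr(check_occlusion(occ$audio, c(w[2], w[2] + 0.3)), "level_db")
  expect_gt(lev, 65)
  expect_identical(a <- simulate_occluded(noise = noise_config(seed = 5))$events$occluded, TRUE)
})
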
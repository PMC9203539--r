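test_that("classification follows the fixed rule order B -> C -> As/Ad -> A", {
  crit <- classification_criteria()
  cls <- function(peak, tpp, ecv = 0.8, flat = FALSE)
    classify_tympanogram(tymp_metrics(peak, tpp, ecv, flat), 9, crit)

  expect_equal(cls(0.0, 0, ecv = 2.5, flat = TRUE), "B")   # patent tube / perforation
  expect_equal(cls(0.7, -225), "C")                        # negative middle-ear pressure
  expect_equal(cls(0.7, 10), "A")
  expect_equal(cls(0.2, 10), "As")
  expect_equal(cls(1.5, 10), "Ad")
  # boundary fixtures for the order: flat wins over C; C wins over As/Ad
  expect_equal(cls(0.05, -225, ecv = 2.0, flat = TRUE), "B")
  expect_equal(cls(0.2, -225), "C")
  expect_equal(cls(1.5, -225), "C")
  # exact cutoffs are not inside the As/Ad bands
  expect_equal(cls(0.3, 10), "A")
  expect_equal(cls(1.4, 10), "A")

  expect_tymp_error(classify_tympanogram(tymp_metrics(0.7, 10, 0.8, FALSE),
                                         age_years = 200),
                    "tymp_domain_error")
  expect_tymp_error(classification_criteria(
    data.frame(age_min = 0, age_max = 10, peak_min = 1, peak_max = 0.5,
               tpp_cutoff = -100)), "tymp_validation_error")
})

test_that("criteria round-trip through JSON", {
  crit <- classification_criteria()
  path <- withr::local_tempfile(fileext = ".json")
  write_criteria(crit, path)
  back <- read_criteria(path)
  expect_equal(back$peak_min, crit$peak_min)
  expect_equal(back$tpp_cutoff, crit$tpp_cutoff)
})

test_that("Bland-Altman statistics match hand computation and are antisymmetric", {
  same <- data.frame(device1 = c(1, 2, 3), device2 = c(1, 2, 3))
  ba0 <- bland_altman(same)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd, 0)

  # hand-computed two-pair example: d = (0.1, -0.1), bias 0, sd = 0.1*sqrt(2)
  two <- data.frame(device1 = c(1.0, 2.0), device2 = c(1.1, 1.9))
  ba <- bland_altman(two)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt((0.1^2 + 0.1^2) / 1), tolerance = 1e-12)
  expect_equal(ba$limits, c(-1.96, 1.96) * ba$sd)

  swapped <- bland_altman(data.frame(device1 = two$device2,
                                     device2 = two$device1))
  expect_equal(swapped$bias, -ba$bias)

  expect_tymp_error(bland_altman(data.frame(device1 = 1, device2 = 2)),
                    "tymp_insufficient_data_error")
  g <- glance(ba)
  expect_named(g, c("bias", "sd", "lower", "upper", "n", "n_outside"))
  expect_s3_class(autoplot(ba), "ggplot")
})

test_that("curve RMSE is computed on the overlapping pressure range only", {
  grid <- tymp_grid()
  a <- tympanogram(data.frame(pressure_daPa = grid, admittance_mL = 1))
  expect_equal(curve_rmse(a, a), 0)
  b <- tympanogram(data.frame(pressure_daPa = grid, admittance_mL = 1.25))
  expect_equal(curve_rmse(a, b), 0.25)

  # one device stops at -300: points below it must not enter the RMSE
  a2 <- a
  a2$admittance_mL[grid < -300] <- 50
  trunc <- tympanogram(data.frame(pressure_daPa = grid[grid >= -300],
                                  admittance_mL = 1.25))
  expect_equal(curve_rmse(a2, trunc), 0.25)
  off_grid <- data.frame(pressure_daPa = grid + 1, admittance_mL = 1)
  expect_tymp_error(curve_rmse(a, off_grid), "tymp_domain_error")
})

test_that("percent agreement counts per rater and averages across raters", {
  all_same <- data.frame(rater = rep(c("r1", "r2"), each = 10),
                         device1 = "A", device2 = "A")
  pa <- percent_agreement(all_same)
  expect_equal(pa$mean_pct, 100)

  one <- data.frame(rater = "r1", device1 = rep("A", 50),
                    device2 = c(rep("A", 43), rep("As", 7)))
  expect_equal(percent_agreement(one)$mean_pct, 100 * 43 / 50)  # = 86

  expect_tymp_error(percent_agreement(data.frame()), "tymp_validation_error")
})

test_that("paired noisy measurements of one ear show no systematic bias", {
  cal <- noisy_cal()
  pairs <- t(vapply(1:200, function(seed) {
    m1 <- analyze_session(
      simulate_session(ear_model("A"), noise = noise_config(seed = seed)),
      cal)$metrics
    m2 <- analyze_session(
      simulate_session(ear_model("A"), noise = noise_config(seed = 5000 + seed)),
      cal)$metrics
    c(m1$peak_admittance, m2$peak_admittance)
  }, numeric(2)))
  ba <- bland_altman(data.frame(device1 = pairs[, 1], device2 = pairs[, 2]))
  # bias indistinguishable from 0 at the 99% level
  expect_lt(abs(ba$bias), 2.6 * ba$sd / sqrt(ba$n))
})
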
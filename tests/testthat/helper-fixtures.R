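# Shared fixtures, built once per test run and cached in the session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, build(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# Ideal (noise-free) cavity battery and the calibration fitted from it.
zero_cavities <- function() fixture("zero_cavities", function() {
  lapply(0:5, function(v) simulate_cavity(v, noise = noise_preset("none")))
})

zero_cal <- function() fixture("zero_cal", function() {
  suppressWarnings(calibrate_device(zero_cavities()))
})

# Default-noise calibration from the seed-0 cavity battery.
noisy_cal <- function() fixture("noisy_cal", function() {
  suppressWarnings(calibrate_device(
    lapply(0:5, function(v) simulate_cavity(v, noise = noise_config(seed = v)))))
})

zero_session_A <- function() fixture("zero_session_A", function() {
  simulate_session(ear_model("A"), noise = noise_preset("none"))
})

expect_tymp_error <- function(expr, class) {
  expect_error(expr, class = class)
}
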
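# Probe-tone DSP primitives shared by sync, seal_monitor and tympanogram.

#' Single-bin probe-tone magnitude
#'
#' Magnitude of the probe-tone bin of an `n_fft`-point FFT of `x` zero-padded
#' (or truncated) to `n_fft` samples. At the default 24 kHz / 24000 points the
#' bins are 1 Hz apart, so bin `freq` is the `freq` Hz bin, and a full-length
#' on-bin sinusoid of amplitude A yields `n_fft * A / 2`. Computed as a direct
#' single-bin DFT (Goertzel-style), which is identical to the FFT bin value
#' because trailing zeros contribute nothing to the sum.
#'
#' @param x Numeric vector of audio samples (length <= `n_fft`; longer input
#'   is truncated).
#' @param freq Probe-tone frequency in Hz (default 226).
#' @param sample_rate Sampling rate in Hz (default 24000).
#' @param n_fft FFT length (default 24000).
#' @return The non-negative bin magnitude.
#' @examples
#' x <- 0.3 * sin(2 * pi * 226 * (0:23999) / 24000)
#' tone_bin_magnitude(x) # 24000 * 0.3 / 2 = 3600
#' @export
tone_bin_magnitude <- function(x, freq = 226, sample_rate = 24000, n_fft = 24000) {
  if (length(x) > n_fft) x <- x[seq_len(n_fft)]
  k <- round(freq * n_fft / sample_rate)
  n <- seq_along(x) - 1
  Mod(sum(x * exp(-2i * pi * k * n / n_fft)))
}

# Design the probe-tone band-pass: 4th-order Butterworth (two-pole prototype
# applied as a band-pass) between band[1] and band[2] Hz.
probe_bandpass <- function(band, sample_rate) {
  nyq <- sample_rate / 2
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    domain_error("band must satisfy 0 < low < high < Nyquist")
  signal::butter(2, band / nyq, type = "pass")
}

bandpass_filter <- function(samples, band, sample_rate) {
  bf <- probe_bandpass(band, sample_rate)
  signal::filtfilt(bf, samples)
}

# Sinusoid amplitude -> dB SPL-equivalent given the trace's full-scale
# reference level. Zero amplitude maps to -Inf.
amplitude_to_db <- function(amplitude, level_reference) {
  ifelse(amplitude > 0, level_reference + 20 * log10(amplitude), -Inf)
}

db_to_amplitude <- function(db, level_reference) 10^((db - level_reference) / 20)
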
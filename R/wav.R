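# Minimal RIFF/WAVE codec for 16-bit PCM mono files, the audio dialect the
# session format uses. Written with readBin/writeBin; chunk-tolerant reader
# (skips LIST/fact etc.), strict about format: PCM, 16-bit, mono.

write_wav_pcm16 <- function(samples, path, sample_rate) {
  if (!is.numeric(samples) || length(samples) < 1L)
    validation_error("WAV samples must be a non-empty numeric vector")
  s <- pmin(pmax(samples, -1), 32767 / 32768)
  pcm <- as.integer(round(s * 32768))
  pcm <- pmin(pmax(pcm, -32768L), 32767L)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

read_wav_pcm16 <- function(path) {
  if (!file.exists(path)) io_error(paste0("WAV file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) format_error("not a RIFF file (field: RIFF magic)")
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) format_error("not a WAVE file (field: WAVE magic)")

  sample_rate <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) format_error("WAV is not PCM (field: audio_format)")
      if (fmt[2] != 1L) format_error("WAV is not mono (field: n_channels)")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")    # byte rate
      readBin(con, integer(), size = 2, endian = "little")    # block align
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) format_error("WAV is not 16-bit (field: bits_per_sample)")
      if (size > 16L) readBin(con, raw(), n = size - 16L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), n = size %/% 2L, size = 2,
                     endian = "little", signed = TRUE)
      samples <- pcm / 32768
    } else {
      readBin(con, raw(), n = size + (size %% 2L))            # skip, pad to even
    }
    if (!is.null(sample_rate) && !is.null(samples)) break
  }
  if (is.null(sample_rate)) format_error("WAV missing fmt chunk (field: fmt)")
  if (is.null(samples) || length(samples) < 1L)
    format_error("WAV missing data chunk (field: data)")
  list(samples = samples, sample_rate = sample_rate)
}
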
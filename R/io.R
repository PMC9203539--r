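# On-disk session format: a directory holding
#   audio.wav     16-bit PCM mono WAV
#   pressure.csv  header time_s,pressure_daPa
#   events.json   session event timestamps/flags
#   motor.csv     optional: time_s,displacement_mm plunger record
#   ground_truth.json  optional: simulator ground truth

#' Read a measurement session from disk
#'
#' @param audio_path Path to a mono 16-bit PCM WAV file, or a session
#'   directory containing `audio.wav`, `pressure.csv` and `events.json`.
#' @param pressure_path Path to the pressure CSV (header
#'   `time_s,pressure_daPa`). Ignored when `audio_path` is a directory.
#' @param events_path Path to the events JSON. Ignored when `audio_path` is a
#'   directory.
#' @param level_reference dB SPL of a full-scale sinusoid (default 85).
#' @return A [tymp_session()].
#' @export
read_session <- function(audio_path, pressure_path = NULL, events_path = NULL,
                         level_reference = 85) {
  motor_path <- truth_path <- NULL
  if (dir.exists(audio_path)) {
    dir <- audio_path
    audio_path <- file.path(dir, "audio.wav")
    pressure_path <- file.path(dir, "pressure.csv")
    events_path <- file.path(dir, "events.json")
    motor_path <- file.path(dir, "motor.csv")
    truth_path <- file.path(dir, "ground_truth.json")
  }
  wav <- read_wav_pcm16(audio_path)
  audio <- audio_trace(wav$samples, wav$sample_rate, level_reference)

  if (!file.exists(pressure_path))
    io_error(paste0("pressure CSV not found: ", pressure_path))
  pd <- utils::read.csv(pressure_path)
  if (!all(c("time_s", "pressure_daPa") %in% names(pd)))
    format_error("pressure CSV must have header time_s,pressure_daPa")
  pressure <- pressure_trace(pd)

  events <- read_events_json(events_path)

  motor <- NULL
  if (!is.null(motor_path) && file.exists(motor_path)) {
    md <- utils::read.csv(motor_path)
    if (!all(c("time_s", "displacement_mm") %in% names(md)))
      format_error("motor CSV must have header time_s,displacement_mm")
    motor <- tibble::as_tibble(md)
  }
  truth <- NULL
  if (!is.null(truth_path) && file.exists(truth_path))
    truth <- read_truth_json(truth_path)

  tymp_session(audio, pressure, events, motor = motor, truth = truth)
}

read_events_json <- function(path) {
  if (!file.exists(path)) io_error(paste0("events JSON not found: ", path))
  ev <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                 error = function(e) format_error(
                   paste0("events JSON is malformed (field: root): ", conditionMessage(e))))
  need <- c("seal_found_t", "sweep_start_notify_t", "sweep_end_notify_t",
            "seal_lost_t", "aborted", "occluded")
  missing <- setdiff(need, names(ev))
  if (length(missing))
    schema_error(paste0("events JSON missing key(s): ", paste(missing, collapse = ", ")))
  session_events(ev$seal_found_t, ev$sweep_start_notify_t,
                 ev$sweep_end_notify_t, ev$seal_lost_t,
                 isTRUE(ev$aborted), isTRUE(ev$occluded))
}

#' Write a measurement session to disk
#'
#' Inverse of [read_session()]: writes `audio.wav`, `pressure.csv`,
#' `events.json` (plus `motor.csv` / `ground_truth.json` when present) into
#' `dir`. Audio round-trips bit-exactly through the 16-bit PCM quantizer.
#'
#' @param session A [tymp_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "tymp_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) io_error(paste0("cannot create directory: ", dir))
  write_wav_pcm16(session$audio$samples, file.path(dir, "audio.wav"),
                  session$audio$sample_rate)
  utils::write.csv(as.data.frame(session$pressure)[, c("time_s", "pressure_daPa")],
                   file.path(dir, "pressure.csv"), row.names = FALSE)
  ev <- unclass(session$events)
  jsonlite::write_json(ev, file.path(dir, "events.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (!is.null(session$motor))
    utils::write.csv(as.data.frame(session$motor),
                     file.path(dir, "motor.csv"), row.names = FALSE)
  if (!is.null(session$truth))
    write_truth_json(session$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

write_truth_json <- function(truth, path) {
  tr <- truth
  if (!is.null(tr$tympanogram_true))
    tr$tympanogram_true <- as.data.frame(tr$tympanogram_true)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "columns")
}

read_truth_json <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(tr$tympanogram_true))
    tr$tympanogram_true <- tympanogram(tibble::as_tibble(tr$tympanogram_true))
  tr
}

#' Write a tympanogram and its metrics to disk
#'
#' Writes a CSV with columns `pressure_daPa,admittance_mL` and, when metrics
#' are supplied, a JSON sidecar `<path minus .csv>_metrics.json`.
#'
#' @param t A [tympanogram()].
#' @param path Output CSV path.
#' @param metrics Optional [tymp_metrics()].
#' @return `path`, invisibly.
#' @export
write_tympanogram <- function(t, path, metrics = NULL) {
  if (!inherits(t, "tympanogram")) t <- tympanogram(t)
  dir <- dirname(path)
  if (!dir.exists(dir)) io_error(paste0("directory does not exist: ", dir))
  utils::write.csv(as.data.frame(t)[, c("pressure_daPa", "admittance_mL")],
                   path, row.names = FALSE)
  if (!is.null(metrics)) {
    mpath <- sub("\\.csv$", "", path)
    jsonlite::write_json(as.list(as.data.frame(metrics)),
                         paste0(mpath, "_metrics.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a tympanogram CSV
#'
#' @param path CSV with columns `pressure_daPa,admittance_mL`.
#' @param calibrated Calibrated flag to attach (default TRUE).
#' @return A [tympanogram()].
#' @export
read_tympanogram <- function(path, calibrated = TRUE) {
  if (!file.exists(path)) io_error(paste0("tympanogram CSV not found: ", path))
  d <- utils::read.csv(path)
  if (!all(c("pressure_daPa", "admittance_mL") %in% names(d)))
    format_error("tympanogram CSV must have header pressure_daPa,admittance_mL")
  tympanogram(d, calibrated = calibrated)
}

#' Read or write a calibration model as JSON
#'
#' The JSON object has keys `p1..p4`, `m`, `b`, `gain_setting`. Unknown extra
#' keys are tolerated with a warning (tolerant reader); missing or
#' non-numeric keys are schema errors.
#'
#' @param path JSON file path.
#' @return [read_calibration()] returns a [calibration_model()];
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) io_error(paste0("calibration JSON not found: ", path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) format_error(
                    paste0("calibration JSON is malformed: ", conditionMessage(e))))
  need <- c("p1", "p2", "p3", "p4", "m", "b", "gain_setting")
  missing <- setdiff(need, names(obj))
  if (length(missing))
    schema_error(paste0("calibration JSON missing key(s): ",
                        paste(missing, collapse = ", ")))
  extra <- setdiff(names(obj), c(need, "amplitude_range"))
  if (length(extra))
    rlang::warn(paste0("calibration JSON has unknown key(s), ignored: ",
                       paste(extra, collapse = ", ")),
                class = "tymp_schema_warning")
  for (k in need) {
    if (!is.numeric(obj[[k]]) || length(obj[[k]]) != 1L || is.na(obj[[k]]))
      schema_error(paste0("calibration key '", k, "' must be a number"))
    obj[[k]] <- as.numeric(obj[[k]])
  }
  rng <- obj$amplitude_range
  if (!is.null(rng)) rng <- as.numeric(rng)
  calibration_model(obj$p1, obj$p2, obj$p3, obj$p4, obj$m, obj$b,
                    obj$gain_setting, amplitude_range = rng)
}

#' @rdname read_calibration
#' @param cal A [calibration_model()].
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_model"))
  out <- cal[c("p1", "p2", "p3", "p4", "m", "b", "gain_setting")]
  if (!is.null(cal$amplitude_range)) out$amplitude_range <- cal$amplitude_range
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
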
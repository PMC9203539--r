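# Canonical fixture battery: every scenario the pipeline must handle, with
# ground truth, written in the on-disk session format.

#' Generate the canonical fixture battery
#'
#' Writes one session directory per scenario: the six calibration cavities
#' (0..5 mL), one ear of each Liden-Jerger type (A, As, Ad, B, C), and the
#' four adverse scenarios (no seal, occluded tip, mid-sweep seal loss, 16 mm
#' abort). Each directory holds `audio.wav`, `pressure.csv`, `events.json`,
#' `motor.csv` and `ground_truth.json`. Deterministic: the same `seed`
#' reproduces the tree byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; per-session seeds are derived as
#'   `seed * 100 + index`.
#' @param noise Base [noise_config()] whose non-seed fields apply to every
#'   session.
#' @return A tibble with columns `name`, `scenario`, `dir`, invisibly usable
#'   as a session index.
#' @export
make_fixture_battery <- function(out_dir, seed = 0L,
                                 noise = noise_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) io_error(paste0("cannot create directory: ", out_dir))
  reseed <- function(i) {
    n <- noise; n$seed <- as.integer(seed * 100L + i); n
  }
  gens <- list(
    cavity_0ml = function(n) simulate_cavity(0, noise = n),
    cavity_1ml = function(n) simulate_cavity(1, noise = n),
    cavity_2ml = function(n) simulate_cavity(2, noise = n),
    cavity_3ml = function(n) simulate_cavity(3, noise = n),
    cavity_4ml = function(n) simulate_cavity(4, noise = n),
    cavity_5ml = function(n) simulate_cavity(5, noise = n),
    ear_A      = function(n) simulate_session(ear_model("A"), noise = n),
    ear_As     = function(n) simulate_session(ear_model("As"), noise = n),
    ear_Ad     = function(n) simulate_session(ear_model("Ad"), noise = n),
    ear_B      = function(n) simulate_session(ear_model("B"), noise = n),
    ear_C      = function(n) simulate_session(ear_model("C"), noise = n),
    no_seal    = function(n) simulate_no_seal(noise = n),
    occluded   = function(n) simulate_occluded(noise = n),
    seal_loss  = function(n) simulate_seal_loss(noise = n),
    abort      = function(n) simulate_abort(noise = n))
  rows <- purrr::imap(gens, function(gen, name) {
    i <- match(name, names(gens))
    s <- gen(reseed(i))
    d <- file.path(out_dir, name)
    write_session(s, d)
    tibble::tibble(name = name, scenario = s$truth$scenario %||% name, dir = d)
  })
  invisible(dplyr::bind_rows(rows))
}
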
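# Liden-Jerger classification and device-agreement statistics.

#' Classification criteria table
#'
#' Age-banded cutoffs for the five Liden-Jerger classes. The shipped defaults
#' are standard literature values — B when the curve is flat, C when the peak
#' sits below -100 daPa, As when the compensated peak is under 0.3 mL, Ad
#' when it exceeds 1.4 mL, A otherwise — applied to all ages; clinics
#' substitute their own table through this object (the criteria file is the
#' interface, not the defaults).
#'
#' @param data Optional data frame with columns `age_min`, `age_max`
#'   (years), `peak_min`, `peak_max` (mL), `tpp_cutoff` (daPa, negative),
#'   `source` (label).
#' @return A tibble of class `classification_criteria`.
#' @export
classification_criteria <- function(data = NULL) {
  if (is.null(data))
    data <- tibble::tibble(age_min = 0, age_max = 150, peak_min = 0.3,
                           peak_max = 1.4, tpp_cutoff = -100,
                           source = "literature defaults (not clinic-specific)")
  need <- c("age_min", "age_max", "peak_min", "peak_max", "tpp_cutoff")
  if (!all(need %in% names(data)))
    validation_error(paste0("criteria needs columns: ", paste(need, collapse = ", ")))
  if (any(data$peak_min >= data$peak_max))
    validation_error("peak_min must be below peak_max")
  if (any(data$tpp_cutoff >= 0))
    validation_error("tpp_cutoff must be negative")
  out <- tibble::as_tibble(data)
  if (!"source" %in% names(out)) out$source <- "custom"
  class(out) <- c("classification_criteria", class(out))
  out
}

#' Read/write classification criteria as JSON
#' @param path JSON file path.
#' @return A [classification_criteria()] / `path` invisibly.
#' @export
read_criteria <- function(path) {
  if (!file.exists(path)) io_error(paste0("criteria JSON not found: ", path))
  classification_criteria(
    tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE)))
}

#' @rdname read_criteria
#' @param criteria A [classification_criteria()].
#' @export
write_criteria <- function(criteria, path) {
  jsonlite::write_json(as.data.frame(criteria), path, digits = NA)
  invisible(path)
}

#' Liden-Jerger classification of tympanogram metrics
#'
#' Fixed rule order: B if the curve is flat; else C if the peak pressure lies
#' below the (age-banded) negative cutoff; else As/Ad if the compensated peak
#' is below/above the admittance cutoffs; else A.
#'
#' @param m A [tymp_metrics()] row.
#' @param age_years Patient age in years (selects the criteria band).
#' @param criteria A [classification_criteria()].
#' @return One of `"A"`, `"As"`, `"Ad"`, `"B"`, `"C"`.
#' @examples
#' m <- tymp_metrics(0.7, -225, 0.8, FALSE)
#' classify_tympanogram(m, age_years = 9) # "C"
#' @export
classify_tympanogram <- function(m, age_years,
                                 criteria = classification_criteria()) {
  stopifnot(inherits(m, "tymp_metrics"))
  band <- criteria[criteria$age_min <= age_years & age_years <= criteria$age_max, ]
  if (nrow(band) == 0L)
    domain_error(sprintf("no classification criteria for age %g years", age_years))
  band <- band[1, ]
  if (isTRUE(m$is_flat)) return("B")
  if (m$peak_pressure < band$tpp_cutoff) return("C")
  if (m$peak_admittance < band$peak_min) return("As")
  if (m$peak_admittance > band$peak_max) return("Ad")
  "A"
}

#' Bland-Altman agreement between two devices
#'
#' Differences are `device2 - device1` with device 1 the reference; bias is
#' their mean, and the 95% limits of agreement are bias +/- 1.96 times the
#' sample SD of the differences.
#'
#' @param data Data frame holding the paired measurements.
#' @param device1,device2 Column names (strings) of the reference and test
#'   device values (defaults `"device1"`, `"device2"`).
#' @return An object of class `bland_altman` with elements `bias`, `sd`,
#'   `limits`, `n`, `n_outside`, and the per-pair tibble `data`
#'   (`mean`, `diff`).
#' @examples
#' ba <- bland_altman(data.frame(device1 = c(1, 2), device2 = c(1.1, 1.9)))
#' ba$bias # 0
#' @export
bland_altman <- function(data, device1 = "device1", device2 = "device2") {
  if (!all(c(device1, device2) %in% names(data)))
    validation_error("data must contain both device columns")
  x <- data[[device1]]; y <- data[[device2]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L)
    insufficient_data("Bland-Altman needs at least 2 complete pairs")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  limits <- bias + c(-1.96, 1.96) * s
  structure(list(bias = bias, sd = s, limits = limits, n = length(d),
                 n_outside = sum(d < limits[1] | d > limits[2]),
                 data = tibble::tibble(mean = (x + y) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4g +/- %.4g (SD), 95%% limits [%.4g, %.4g], n = %d (%d outside)\n",
              x$bias, x$sd, x$limits[1], x$limits[2], x$n, x$n_outside))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) x$data

#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd = x$sd, lower = x$limits[1],
                 upper = x$limits[2], n = x$n, n_outside = x$n_outside)
}

#' RMSE between two tympanograms over their overlapping pressure range
#'
#' @param t1,t2 [tympanogram()]s (or data frames with `pressure_daPa`,
#'   `admittance_mL`).
#' @return RMSE in mL, computed only on grid pressures present in both.
#' @export
curve_rmse <- function(t1, t2) {
  j <- dplyr::inner_join(
    tibble::as_tibble(t1)[, c("pressure_daPa", "admittance_mL")],
    tibble::as_tibble(t2)[, c("pressure_daPa", "admittance_mL")],
    by = "pressure_daPa", suffix = c("_1", "_2"))
  if (nrow(j) == 0L)
    domain_error("tympanograms have no overlapping pressure values")
  sqrt(mean((j$admittance_mL_1 - j$admittance_mL_2)^2))
}

#' Percent agreement between paired classifications across raters
#'
#' @param ratings Data frame with columns `rater`, `device1`, `device2`
#'   (class labels per paired curve).
#' @return A list of class `percent_agreement`: `mean_pct`, `sd_pct`, and the
#'   per-rater tibble `per_rater` (`rater`, `n`, `agreement_pct`).
#' @examples
#' r <- data.frame(rater = rep(1, 50),
#'                 device1 = rep("A", 50),
#'                 device2 = c(rep("A", 43), rep("As", 7)))
#' percent_agreement(r)$mean_pct # 86
#' @export
percent_agreement <- function(ratings) {
  need <- c("rater", "device1", "device2")
  if (!is.data.frame(ratings) || !all(need %in% names(ratings)))
    validation_error("ratings needs columns rater, device1, device2")
  if (nrow(ratings) == 0L) validation_error("ratings is empty (zero raters)")
  if (anyNA(ratings[need])) validation_error("ratings contains missing labels")
  per <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ratings), .data$rater),
    n = dplyr::n(),
    agreement_pct = 100 * mean(.data$device1 == .data$device2),
    .groups = "drop")
  structure(list(mean_pct = mean(per$agreement_pct),
                 sd_pct = if (nrow(per) > 1L) stats::sd(per$agreement_pct) else 0,
                 per_rater = per),
            class = "percent_agreement")
}

#' @export
print.percent_agreement <- function(x, ...) {
  cat(sprintf("<percent_agreement> %.1f +/- %.1f %% across %d rater(s)\n",
              x$mean_pct, x$sd_pct, nrow(x$per_rater)))
  invisible(x)
}
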
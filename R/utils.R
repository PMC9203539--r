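# Classed error helpers. Every reader/validator raises one of these so
# callers (and tests) can match on condition class rather than message text.

tymp_error <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "tymp_error"), ...)
}

format_error        <- function(msg) tymp_error(msg, "tymp_format_error")
validation_error    <- function(msg) tymp_error(msg, "tymp_validation_error")
schema_error        <- function(msg) tymp_error(msg, "tymp_schema_error")
domain_error        <- function(msg) tymp_error(msg, "tymp_domain_error")
insufficient_data   <- function(msg) tymp_error(msg, "tymp_insufficient_data_error")
fit_error           <- function(msg) tymp_error(msg, "tymp_fit_error")
sync_error          <- function(msg) tymp_error(msg, "tymp_sync_error")
io_error            <- function(msg) tymp_error(msg, "tymp_io_error")
calibration_error   <- function(msg) tymp_error(msg, "tymp_calibration_error")
physical_limit_error <- function(msg) tymp_error(msg, "tymp_physical_limit_error")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Least-squares slope of y on x (closed form; >= 2 distinct x required).
ls_slope <- function(x, y) {
  xc <- x - mean(x)
  s2 <- sum(xc^2)
  if (s2 <= 0) return(0)
  sum(xc * (y - mean(y))) / s2
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
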
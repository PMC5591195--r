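# internal argument checking and condition helpers

.smsweep_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "smsweep_error", "error")))
}

invalid_arg <- function(msg) .smsweep_error(msg, "smsweep_invalid_argument")
insufficient_data <- function(msg) .smsweep_error(msg, "smsweep_insufficient_data")
fit_failure <- function(msg) .smsweep_error(msg, "smsweep_fit_failure")
calibration_failure <- function(msg) .smsweep_error(msg, "smsweep_calibration_failure")
validation_error <- function(msg) .smsweep_error(msg, "smsweep_validation_error")

.check_scalar <- function(x, name, min = -Inf, strict = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    invalid_arg(sprintf("`%s` must be a single finite number", name))
  if (strict && x <= min)
    invalid_arg(sprintf("`%s` must be > %g", name, min))
  if (!strict && x < min)
    invalid_arg(sprintf("`%s` must be >= %g", name, min))
  if (integerish && abs(x - round(x)) > 1e-8)
    invalid_arg(sprintf("`%s` must be a whole number", name))
  invisible(TRUE)
}
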
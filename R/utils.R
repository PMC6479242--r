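# internal helpers shared across modules

# stop with a classed condition so callers/tests can match on class
pk_abort <- function(message, class) {
  abort(message, class = c(class, "pkcross_error"))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) {
    pk_abort(sprintf("`%s` must be a single finite number.", name),
             "pkcross_error_value")
  }
  if (positive && x <= 0) {
    pk_abort(sprintf("`%s` must be > 0.", name), "pkcross_error_value")
  }
  invisible(x)
}

# lognormal sdlog giving a coefficient of variation of cv_pct percent
cv_to_sdlog <- function(cv_pct) {
  sqrt(log(1 + (cv_pct / 100)^2))
}

# geometric mean of strictly positive values
geo_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L || any(x <= 0)) return(NA_real_)
  exp(mean(log(x)))
}

# sample CV% using the n-1 standard deviation, the clinical-PK convention
cv_pct <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  100 * sd(x) / mean(x)
}
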
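# internal argument checks ----------------------------------------------

stop_bad_arg <- function(name, msg) {
  stop(sprintf("`%s` %s", name, msg), call. = FALSE)
}

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad_arg(name, "must be a single finite number")
  }
  if (positive && x <= 0) stop_bad_arg(name, "must be > 0")
  if (nonneg && x < 0) stop_bad_arg(name, "must be >= 0")
  invisible(x)
}

check_count <- function(x, name) {
  check_scalar_number(x, name, positive = TRUE)
  if (x != as.integer(x)) stop_bad_arg(name, "must be a whole number")
  as.integer(x)
}

check_numeric_vec <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x))) {
    stop_bad_arg(name, "must be a non-empty finite numeric vector")
  }
  if (positive && any(x <= 0)) stop_bad_arg(name, "must be > 0 throughout")
  if (nonneg && any(x < 0)) stop_bad_arg(name, "must be >= 0 throughout")
  invisible(x)
}

# lognormal sdlog giving a fractional coefficient of variation `cv`
cv_to_sdlog <- function(cv) sqrt(log1p(cv^2))

# percent CV of a numeric vector; NA when fewer than 2 values
percent_cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
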
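# Internal condition helpers: every user-facing failure is a classed condition
# so callers (and the CLI) can distinguish validation, format, sequencing,
# domain, calibration and protocol errors.

abort_hua <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "hua_error")))
}

abort_validation  <- function(msg) abort_hua(msg, "hua_validation_error")
abort_format      <- function(msg) abort_hua(msg, "hua_format_error")
abort_sequencing  <- function(msg) abort_hua(msg, "hua_sequencing_error")
abort_domain      <- function(msg) abort_hua(msg, "hua_domain_error")
abort_calibration <- function(msg) abort_hua(msg, "hua_calibration_error")
abort_degenerate  <- function(msg) abort_hua(msg, "hua_degenerate_error")
abort_protocol    <- function(msg) abort_hua(msg, "hua_protocol_error")
abort_config      <- function(msg) abort_hua(msg, "hua_config_error")

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("`%s` must be a single finite number", name))
  if (x < lo || x > hi)
    abort_validation(sprintf("`%s` = %g is outside [%g, %g]", name, x, lo, hi))
  invisible(as.numeric(x))
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Run expr under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort_validation("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# round half away from zero (prose-style integer percents; R's round() is
# round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
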
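stopf <- function(fmt, ..., class = "distractr_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "distractr_error")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x)))
    stopf("`%s` must be a single finite number", name,
          class = "distractr_invalid_argument")
  if (!is.na(x) && (x < lower || x > upper))
    stopf("`%s` = %g is outside [%g, %g]", name, x, lower, upper,
          class = "distractr_invalid_argument")
  invisible(x)
}

#' Trapezoidal integration
#'
#' @param x ordinate grid (increasing).
#' @param y values at `x`.
#' @return The trapezoid-rule integral.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Derive a per-session seed from a cohort seed
#'
#' Deterministic counter scheme: `(seed * 1009 + counter) mod (2^31 - 1)`,
#' so cohorts are reproducible session by session (e.g. under parallel
#' generation) from a single integer seed.
#'
#' @param seed integer base seed.
#' @param counter non-negative integer session counter.
#' @return An integer seed below 2^31.
#' @export
session_seed <- function(seed, counter) {
  check_scalar(seed, "seed")
  check_scalar(counter, "counter", lower = 0)
  as.integer((as.double(seed) %% 2147483647 * 1009 + counter) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
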
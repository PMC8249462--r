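#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.0625 -> 0.063 at 3 digits), the
#' convention used for reported inbreeding coefficients. Base `round()`
#' rounds half to even and would turn 0.0625 into 0.062.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## monitoring years run May 1 - Apr 30 and are labeled by starting year
monitoring_year <- function(date) {
  d <- as.Date(date)
  y <- as.integer(format(d, "%Y"))
  ifelse(as.integer(format(d, "%m")) >= 5L, y, y - 1L)
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a non-missing scalar", name), call. = FALSE)
  invisible(x)
}
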
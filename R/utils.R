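#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used when
#' formatting NORSE report tables (e.g. 7.65 rounds to 7.7, -7.65 to -7.7).
#' Base \code{round()} rounds half to even, which does not reproduce the
#' arithmetic of printed ranking tables. A small guard absorbs binary
#' floating-point representation error in decimal inputs.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return numeric vector, rounded.
#' @export
#' @examples
#' round_half_away(c(7.65, -7.65, 28.35), 1)
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# population standard deviation (divide by n); the sample convention is
# available where a caller asks for it
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

stat_sd <- function(x, type = c("population", "sample")) {
  type <- match.arg(type)
  if (type == "population") sd_pop(x) else stats::sd(x, na.rm = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_norse <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "norse_error")))
}
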
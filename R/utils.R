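#' Round half away from zero
#'
#' Percentages in quality reports are rounded half-up to one decimal, the
#' convention used in published pre/post comparison tables (base R's
#' `round()` rounds half to even, which would print 12.25 as 12.2).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent with one-decimal rounding
#' @keywords internal
#' @noRd
pct1 <- function(count, total) {
  round_half_up(100 * count / total, 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_jjdq <- function(msg, class) {
  rlang::abort(msg, class = c(class, "jjdq_error"))
}
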
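#' Decimal half-up rounding
#'
#' Rounds to a fixed number of decimal places with ties going away from zero,
#' the convention used for all displayed frequencies, percentages and rates in
#' this package. Base [round()] uses round-half-even, which does not reproduce
#' printed cohort summaries deterministically.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (may be negative for tens, hundreds).
#' @return numeric vector rounded half-up at `digits`.
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) == 2
#' round_half_up(0.0016075, 5)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by one ulp so values like 43.55 stored as 43.54999... still round up
  z <- abs(x) * p
  z <- floor(z + 0.5 + sqrt(.Machine$double.eps))
  sign(x) * z / p
}

# internal: fixed-decimal display string
fmt_fixed <- function(x, digits) {
  formatC(round_half_up(x, digits), format = "f", digits = max(digits, 0))
}

# internal: stop with a consistent invalid-input condition
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("founderhap_invalid_input", "error")))
}
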
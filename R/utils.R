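#' Round half away from zero
#'
#' Decimal rounding with ties going up (away from zero), the convention used
#' for reported repeat frequencies such as 10.3 Hz. Base [round()] rounds
#' half to even, which differs at exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# internal: stop with the caller's message, no call in the condition
fail <- function(...) stop(..., call. = FALSE)

# internal: check scalar positive number
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    fail(name, " must be a single positive number")
  invisible(x)
}
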
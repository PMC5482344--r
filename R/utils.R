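#' Round half away from zero
#'
#' Base [round()] rounds half to even (banker's rounding), so
#' `round(0.8125, 3)` gives `0.812`. Reported completeness values and CLI
#' output use conventional half-up rounding instead, under which 26/32
#' prints as `0.813` at three decimals.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 3).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(26 / 32, 3)
round_half_up <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

abort_invalid <- function(message, ...) {
  rlang::abort(message, class = "ternet_invalid_input", ...)
}

abort_lookup <- function(message, ...) {
  rlang::abort(message, class = "ternet_lookup_error", ...)
}

abort_conflict <- function(message, ...) {
  rlang::abort(message, class = "ternet_conflict_error", ...)
}

abort_format <- function(message, ...) {
  rlang::abort(message, class = "ternet_format_error", ...)
}

`%||%` <- rlang::`%||%`
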
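#' Interaction status levels
#'
#' Every drug-target pair in an edge-colored network carries exactly one of
#' three statuses: `"active"`, `"inactive"`, or `"unknown"`. Active and
#' inactive statuses come from experimental or computational determination;
#' unknown status arises only from absence of data (unknown-by-omission).
#'
#' @format A character vector of the three status levels, in canonical order.
#' @export
#' @examples
#' dt_statuses
dt_statuses <- c("active", "inactive", "unknown")

as_status <- function(x, what = "status") {
  x <- tolower(trimws(as.character(x)))
  bad <- !is.na(x) & !x %in% dt_statuses
  if (any(bad)) {
    abort_invalid(sprintf(
      "invalid %s value(s): %s (must be one of %s)",
      what, paste(unique(x[bad]), collapse = ", "),
      paste(dt_statuses, collapse = "/")
    ))
  }
  x
}

#' Classify a measured activity value against a potency threshold
#'
#' Converts a quantitative activity readout (canonically a potency such as an
#' IC50 or Ki, in micromolar) into a binary active/inactive status. With
#' `direction = "at_most"` (the potency convention: lower values mean stronger
#' activity) a value is active when it is less than or equal to the threshold;
#' with `direction = "at_least"` it is active when greater than or equal to
#' the threshold. The boundary is inclusive either way. Classification never
#' yields `"unknown"`: unknown status arises only from absent data.
#'
#' @param value Numeric vector of non-negative, finite activity values (uM).
#' @param threshold Single non-negative, finite threshold (uM). Thresholds of
#'   1-10 uM are typical for potency readouts; the default is 10.
#' @param direction `"at_most"` (default; active when `value <= threshold`)
#'   or `"at_least"` (active when `value >= threshold`).
#' @return Character vector of `"active"`/`"inactive"`, same length as
#'   `value`.
#' @export
#' @examples
#' classify_activity(c(0.5, 15, 10), threshold = 10)
#' classify_activity(12, threshold = 10, direction = "at_least")
classify_activity <- function(value, threshold = 10,
                              direction = c("at_most", "at_least")) {
  direction <- match.arg(direction)
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0)) {
    abort_invalid("`value` must be finite and >= 0")
  }
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      !is.finite(threshold) || threshold < 0) {
    abort_invalid("`threshold` must be a single finite value >= 0")
  }
  active <- switch(direction,
    at_most  = value <= threshold,
    at_least = value >= threshold
  )
  ifelse(active, "active", "inactive")
}
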
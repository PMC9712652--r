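# Internal condition helpers. Three error classes are used throughout:
#   tinburden_config_error     -- bad configuration / parameters
#   tinburden_format_error     -- malformed external file
#   tinburden_validation_error -- values violating a documented invariant
abort_config <- function(msg, ...) {
  abort(msg, class = "tinburden_config_error", ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = "tinburden_format_error", ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "tinburden_validation_error", ...)
}

notify <- function(msg) {
  inform(msg, class = "tinburden_notice")
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x > 0 && x == as.integer(x)
}

is_prob <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Format a p-value for report display
#'
#' Values below 0.001 are rendered `"<0.001"`; larger values with three
#' significant digits.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
#' @examples
#' fmt_p(c(3e-24, 0.0403, 1))
fmt_p <- function(p) {
  ifelse(is.na(p), "NA",
    ifelse(p < 0.001, "<0.001", formatC(p, digits = 3, format = "g"))
  )
}

# "21 (0.216)" cells: carrier count with frequency to 3 decimals.
fmt_freq_cell <- function(count, total) {
  sprintf("%d (%s)", count, formatC(count / total, digits = 3, format = "f"))
}

# "62 (64%)" cells: count with whole-number percentage.
fmt_pct_cell <- function(count, total) {
  sprintf("%d (%d%%)", count, as.integer(round(100 * count / total)))
}
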
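#' Round half away from zero
#'
#' Clinical tables conventionally round halves up (away from zero), unlike
#' [base::round()]'s round-half-to-even. A tiny epsilon guards against
#' binary-representation error in values such as `0.15` before the halving
#' decision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1, the convention used for
#'   calculated stenosis scores and reported percentages).
#' @return Numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(c(1.65, 2.25, -1.65), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count, rounded to one decimal
#'
#' @param k Count of interest.
#' @param n Total count; must be positive.
#' @param digits Decimal places (default 1).
#' @return `100 * k / n`, rounded half-up.
#' @examples
#' percent_of(2602, 3000) # 86.7
#' @export
percent_of <- function(k, n, digits = 1) {
  if (any(n <= 0)) {
    abort_domain("`n` must be positive to form a percentage.")
  }
  round_half_up(100 * k / n, digits)
}

abort_validation <- function(message, ...) {
  rlang::abort(message, class = "casus_validation_error", ...)
}

abort_domain <- function(message, ...) {
  rlang::abort(message, class = "casus_domain_error", ...)
}

abort_computation <- function(message, ...) {
  rlang::abort(message, class = "casus_computation_error", ...)
}

`%||%` <- rlang::`%||%`
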
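`%||%` <- function(x, y) if (is.null(x)) y else x

#' Exact half-up percentage
#'
#' Computes `100 * numerator / denominator` rounded half-up to the
#' requested number of decimals, using integer arithmetic so that every
#' printed (count, denominator) pair reproduces exactly (base `round()`
#' uses round-half-to-even and cannot).
#'
#' @param numerator Non-negative integer vector.
#' @param denominator Positive integer (vectorized).
#' @param decimals Number of decimals to keep (default 1).
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' percentage(935, 4420) # 21.2
#' percentage(178, 4420, decimals = 0) # 4
percentage <- function(numerator, denominator, decimals = 1) {
  if (any(is.na(denominator)) || any(denominator <= 0)) {
    stop("denominator must be a positive integer", call. = FALSE)
  }
  if (any(is.na(numerator)) || any(numerator < 0)) {
    stop("numerator must be non-negative", call. = FALSE)
  }
  p <- as.numeric(numerator) * 100 * 10^decimals
  q <- as.numeric(denominator)
  whole <- p %/% q
  rem <- p - whole * q
  up <- (2 * rem) >= q
  (whole + as.numeric(up)) / 10^decimals
}
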
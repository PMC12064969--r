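#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (half-up), the
#' convention used for all reported percentages. Base R's [round()] rounds
#' half to even, which would turn 0.5 into 0 — not what descriptive tables
#' in this field print.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) is 2
#' round_half_up(43.796, 1)  # 43.8
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by a relative epsilon so values like 43.75 stored as 43.74999...
  # still round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Percentage with half-up rounding
#'
#' Computes `100 * numerator / denominator` rounded half-up at the stated
#' precision — the arithmetic behind every percentage in the descriptive
#' summaries.
#'
#' @param numerator,denominator Non-negative counts; `numerator <= denominator`.
#' @param decimals Decimal places to keep (default 1).
#' @return Numeric vector of percentages.
#' @examples
#' percentage(1179, 2692)  # 43.8
#' percentage(102, 1179)   # 8.7
#' @export
percentage <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) {
    abort("percentage() is undefined for a zero or negative denominator")
  }
  if (any(numerator < 0) || any(numerator > denominator)) {
    abort("numerator must satisfy 0 <= numerator <= denominator")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

# internal: random base-36 strings (not cryptographic; used by the generator)
random_base36 <- function(n, width) {
  chars <- c(letters, 0:9)
  vapply(
    seq_len(n),
    function(i) paste(sample(chars, width, replace = TRUE), collapse = ""),
    character(1)
  )
}
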
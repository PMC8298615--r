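#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero, unlike [base::round()]'s
#' round-half-to-even. This is the convention used throughout the package for
#' "1 in N" figures and percent displays, because it reproduces the printed
#' cells of published allele-frequency tables.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep (may be negative).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_away(0.5)    # 1, not 0
#' round_half_away(2.5)    # 3
#' round_half_away(-2.5)   # -3
#' round_half_away(63.8888, 1)  # 63.9
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Express a frequency as a percentage
#'
#' Multiplies a frequency in `[0, 1]` by 100 and rounds half away from zero,
#' matching the display convention of allele-frequency tables (e.g. 7/2730
#' prints as 0.26, 1299/107928 as 1.2).
#'
#' @param f frequency (fraction) in `[0, 1]`.
#' @param decimals number of decimal places.
#' @return numeric percentage.
#' @examples
#' percent(7 / 2730, 2)        # 0.26
#' percent(1299 / 107928, 1)   # 1.2
#' @export
percent <- function(f, decimals = 2) {
  stopifnot(is.numeric(f), all(is.na(f) | (f >= 0 & f <= 1)))
  round_half_away(f * 100, decimals)
}

# "1 in N" with thousands separators for human-readable output
format_one_in <- function(n) {
  ifelse(is.na(n), "not observed",
         paste0("1 in ", formatC(n, format = "d", big.mark = ",")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
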
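#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used in printed mortality tables.
#' Base R's `round()` rounds half to even, which changes boundary cases like
#' 0.005; reported percentages here follow the half-up convention instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.005, 2.675, -0.005), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by a few ulp so values stored as ...49999 from decimal literals
  # still round up
  sign(x) * trunc(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Format a percentage the way the study tables print it
#'
#' @param x Proportion in `[0, 1]`.
#' @param digits Decimal places (2 for tables, 1 for prose-style exports).
#' @return Numeric percentage rounded half-up.
#' @export
as_pct <- function(x, digits = 2) {
  round_half_up(100 * x, digits)
}

fmt_count <- function(n) formatC(n, format = "d", big.mark = ",")

fmt_pct <- function(x, digits = 2) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' @keywords internal
abort_somward <- function(msg, class) {
  rlang::abort(msg, class = paste0("somward_", class))
}

# ICD-10: one letter, two digits, up to two further alphanumerics
ICD10_PATTERN <- "^[A-Z][0-9]{2}[A-Z0-9]{0,2}$"

#' Check ICD-10 code syntax
#'
#' A syntactically valid code is a capital letter, two digits, and up to two
#' additional alphanumeric characters (e.g. `"I25"`, `"I251"`, `"C349"`).
#'
#' @param code Character vector of candidate codes.
#' @return Logical vector.
#' @export
is_valid_icd10 <- function(code) {
  !is.na(code) & grepl(ICD10_PATTERN, code)
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x
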
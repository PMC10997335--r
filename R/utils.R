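#' Canonicalize free-text strings
#'
#' FAERS free text is inconsistently cased and padded; drug names and
#' preferred terms are compared in a case-folded, whitespace-squeezed form.
#'
#' @param x Character vector.
#' @return Character vector, lower-cased, trimmed, internal whitespace
#'   collapsed to single spaces. `NA` stays `NA`.
#' @export
#' @examples
#' canon_str(c("  Torsade  de Pointes ", "DIFLUCAN"))
canon_str <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out <- gsub("\\s+", " ", out)
  out[!nzchar(out) & !is.na(out)] <- NA_character_
  out
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all printed percentages so that
#' e.g. 42.385 prints as 42.39 rather than banker's-rounded 42.38.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count, rounded half-up
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Decimal places (default 2, the convention used throughout).
#' @return `100 * num / den`, rounded half-up; `NA` when `den` is 0.
#' @export
pct <- function(num, den, digits = 2) {
  out <- round_half_up(100 * num / den, digits)
  out[den == 0] <- NA_real_
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# internal: stop with a stage-prefixed message (pipeline error reporting)
stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
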
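# Shared vocabularies and small numeric helpers.

zr_elements <- c("premaxilla", "maxilla", "dentary")
zr_sides <- c("left", "right")
zr_classes <- c("functional", "replacement")
zr_stages <- c("early_juvenile", "late_juvenile", "subadult", "unknown")
# `empty_alveolus` marks a replacement tooth sitting in an alveolus whose
# functional tooth is already shed; it is the only way such a record passes
# validation.
zr_flags <- c("newly_erupted", "worn", "remnant_present", "empty_alveolus")

#' Round half away from zero
#'
#' Published dentition tables round half away from zero (2.655 prints as
#' 2.66), whereas base [round()] rounds half to even. All rounded values the
#' package reports go through this helper.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` places, ties moving away from zero.
#' @examples
#' round_half_up(2.655, 2)
#' round_half_up(2.4775, 3)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by a relative epsilon so that decimal values stored just below a
  # .5 boundary (e.g. 2.655 -> 2.65499999...) still round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

zr_abort <- function(message, class, ...) {
  abort(message, class = c(class, "zr_error"), ...)
}

# split a ';'-separated flag string into a character vector
parse_flags <- function(flags) {
  if (is.na(flags) || !nzchar(flags)) return(character())
  trimws(strsplit(flags, ";", fixed = TRUE)[[1]])
}

#' Test whether a flag is set on a tooth record
#'
#' Flags are stored as a single `;`-separated string column (e.g.
#' `"newly_erupted;worn"`).
#'
#' @param flags Character vector of flag strings (possibly `NA`).
#' @param flag Single flag name to test for.
#' @return Logical vector.
#' @export
has_flag <- function(flags, flag) {
  vapply(flags, function(f) {
    !is.na(f) && flag %in% parse_flags(f)
  }, logical(1), USE.NAMES = FALSE)
}

# fractional part in [0, 1)
frac <- function(x) x - floor(x)
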
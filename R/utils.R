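#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used in the reporting layer
#' (base \code{round()} rounds half to even). Applied only when formatting
#' tables; internal values are kept at full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(2.345, 2)  # 2.35, not 2.34
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  p <- 10^digits
  # tiny offset guards against values like 41.665 stored as 41.66499999...
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-9) / p
}

# shared input checks ---------------------------------------------------

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  }
  invisible(x)
}

PREY_STAGES <- c("nymph_4_5", "adult")
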
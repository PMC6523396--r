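#' Round half away from zero
#'
#' Fixed-point rounding where a trailing 5 always rounds up (half-up), the
#' convention used throughout the rendered concordance tables. Base
#' [round()] rounds half to even, which disagrees with half-up at exactly
#' half-way values (e.g. 79.1665 at 3 decimals).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny epsilon guards binary representation of values like x*p = 94594.49999...
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' @keywords internal
fmt_thousands <- function(x) {
  format(x, big.mark = ",", scientific = FALSE, trim = TRUE)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() wrapper that never truncates the offender list
#' @keywords internal
tg_stop <- function(...) stop(paste0(...), call. = FALSE)
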
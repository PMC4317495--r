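#' Round half away from zero
#'
#' Integer rounding used for all printed percentages. Unlike [base::round()],
#' which rounds half to even, halves are rounded away from zero, the
#' convention of most spreadsheet and figure-preparation software.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5, 63.66))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# stop() with the calling function's name stripped of the internal frame
.fail <- function(...) stop(..., call. = FALSE)

.assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .fail(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    .fail(sprintf("'%s' must be positive", name))
  invisible(x)
}
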
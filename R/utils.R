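#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for displayed rupee amounts and
#' percentages. Base [round()] rounds half to even, which does not match
#' how prices and survey tables are typically printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by a few ulp so values stored just under .5 (e.g. 0.1272 * 100)
  # are not pushed the wrong way by binary representation
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("cvdburden_invalid_input", "error")))
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("cvdburden_domain_error", "error")))
}

check_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_invalid(name, " must be a single number")
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!lo_ok || !hi_ok)
    stop_invalid(name, " = ", format(x), " is outside the admissible range")
  invisible(x)
}

cvd_extdata <- function(file) {
  path <- system.file("extdata", file, package = "cvdburden")
  if (!nzchar(path)) stop("extdata file not found: ", file)
  path
}
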
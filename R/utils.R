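# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base [round()] uses banker's rounding; report tables here follow the
#' commercial convention (0.5 always rounds up in magnitude), e.g. a saving of
#' 10.25% prints as 10.3.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return `x` rounded half-up (half away from zero) to `digits` places.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.25, -0.5), 0:1 * 0)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort("'%s' must be a single non-missing number", name)
  if (x < min || x > max)
    abort("'%s' must be in [%s, %s], got %s", name, min, max, x)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    abort("'%s' must be TRUE or FALSE", name)
  invisible(x)
}

# seconds between timestamps, robust to POSIXct/numeric
secs_between <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "secs"))
}
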
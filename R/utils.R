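#' Percent change between two reported means
#'
#' The reporting convention used throughout the package is
#' \code{100 * (old - new) / old}: a positive value is a decline from
#' \code{old} to \code{new}, a negative value an increase. For report tables
#' the result is rounded half-up to the nearest integer, so that e.g. a drop
#' from 3.1 to 2.0 g cm^-2 yr^-1 is reported as 35(%).
#'
#' @param old reference (earlier) value; must be non-zero.
#' @param new later value.
#' @param rounded if \code{TRUE} (default) round half-up to an integer
#'   percentage; otherwise return the raw percentage.
#' @return numeric percentage (vectorised).
#' @examples
#' percent_change(3.1, 2.0)   # 35
#' percent_change(18.2, 16.7) # 8
#' @export
percent_change <- function(old, new, rounded = TRUE) {
  stopifnot(is.numeric(old), is.numeric(new))
  if (any(old == 0)) stop("percent change undefined for a zero reference value")
  pct <- 100 * (old - new) / old
  if (rounded) round_half_up(pct) else pct
}

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; report tables use the ordinary
#' "round half up" convention instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# internal: stop() with a consistent prefix when a scalar check fails
.check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name))
  if (x < lower || x > upper)
    stop(sprintf("'%s' = %g outside [%g, %g]", name, x, lower, upper))
  invisible(x)
}

# internal: seed-derived sub-stream seeds, kept within 32-bit integer range
.substream_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}
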
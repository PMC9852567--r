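#' @importFrom tibble tibble as_tibble
#' @importFrom stats qbeta rbinom rpois rlnorm rnorm runif median pnorm qnorm
#'   wilcox.test setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Decimal rounding in which ties are rounded away from zero (so 0.5 -> 1,
#' 2.5 -> 3), matching how percentages are conventionally printed in clinical
#' reports. Base R's `round()` rounds half to even and would print 13.5% as
#' 14% or 12.5% as 12% inconsistently with that convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## percent formatting used by the reporting layer: integer percent by default,
## one decimal for sample-size style calculations
format_percent <- function(p, digits = 0) {
  paste0(format(round_half_up(100 * p, digits), nsmall = digits, trim = TRUE), "%")
}

format_ci <- function(lower, upper, digits = 0) {
  lo <- format(round_half_up(100 * lower, digits), nsmall = digits, trim = TRUE)
  hi <- format(round_half_up(100 * upper, digits), nsmall = digits, trim = TRUE)
  paste0(lo, "-", hi, "%")
}

## Deterministic sub-stream seeds: every sample/stage derives its own seed from
## the root so that adding samples never perturbs draws for earlier ones.
## Kept strictly below 2^31 (R integers are 32-bit); doubles are exact here
## because all intermediates stay below 2^53.
derive_seed <- function(seed, stream, index = 0L) {
  stream_code <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  x <- (as.numeric(seed) %% 2147483647) * 48271 + stream_code * 7919 + as.numeric(index)
  as.integer(x %% 2147483629 + 1)
}

stop_urovaf <- function(msg, class, data = list()) {
  cond <- structure(
    class = c(class, "urovaf_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
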
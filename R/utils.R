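#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used for
#' all reported percentages (base \code{round()} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(0.5)    # 1
#' round_half_up(-0.5)   # -1
#' round_half_up(76.47)  # 76
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stopifnot-style check with a formatted message
.check <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# derive a stream-specific 31-bit seed from a master seed, so independent
# stages (generation, null models, permutations) never share a stream
.derive_seed <- function(seed, stream) {
  .check(is.numeric(seed) && length(seed) == 1L, "seed must be a single number")
  offsets <- c(generate = 11L, null_model = 211L, permutation = 311L,
               calibration = 411L, pilot = 511L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 1009 + off) %% .Machine$integer.max)
}
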
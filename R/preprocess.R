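#' Saturation limits for contrast stretching
#'
#' @param low_tail fraction of pixels saturated at the bottom, in `[0, 0.5)`.
#' @param high_tail upper quantile, in `(0.5, 1]`.
#' @return An object of class `stretch_limits`.
#' @export
stretch_limits <- function(low_tail = 0.01, high_tail = 0.99) {
  if (!is.numeric(low_tail) || !is.numeric(high_tail) ||
      low_tail < 0 || low_tail >= 0.5 || high_tail <= 0.5 || high_tail > 1)
    stop("require 0 <= low_tail < 0.5 < high_tail <= 1", call. = FALSE)
  structure(list(low_tail = low_tail, high_tail = high_tail),
            class = "stretch_limits")
}

# deterministic order-statistic quantile: value at rank ceiling(q * N)
order_quantile <- function(sorted, q) {
  n <- length(sorted)
  sorted[max(1L, min(n, ceiling(q * n)))]
}

#' Percentile contrast stretching
#'
#' Linearly maps the intensity range between the per-image low and high
#' saturation quantiles (defaults 0.01 and 0.99) onto the full `[0, 1]`
#' dynamic range, clipping the saturated tails. The mapping is monotone
#' non-decreasing, with gamma 1. A degenerate image whose two quantiles
#' coincide is returned unchanged with a warning.
#'
#' @param img a [gray_image()] or numeric matrix in `[0, 1]`.
#' @param limits a [stretch_limits()].
#' @return A [gray_image()] of the same dimensions.
#' @examples
#' ramp <- gray_image(matrix(seq(0, 1, length.out = 100), 10, 10))
#' out <- enhance_contrast(ramp)
#' range(out$pixels)
#' @export
enhance_contrast <- function(img, limits = stretch_limits()) {
  g <- as_gray_image(img)
  p <- g$pixels
  s <- sort(as.vector(p))
  lo <- order_quantile(s, limits$low_tail)
  hi <- order_quantile(s, limits$high_tail)
  if (hi <= lo) {
    warning("degenerate intensity range; image returned unchanged",
            call. = FALSE)
    return(g)
  }
  out <- (p - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  gray_image(out, levels = g$levels)
}
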
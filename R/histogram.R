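#' Gray-level histogram
#'
#' Container for the 256-bin occurrence counts `r` (bin m holds the number of
#' pixels whose quantized level is m) and the normalized probabilities
#' `h = r / (U*V)`.
#'
#' @param counts integer vector of length 256 of non-negative counts.
#' @return An object of class `gray_histogram` with fields `counts`, `probs`
#'   and `levels`.
#' @export
gray_histogram <- function(counts) {
  if (length(counts) != 256L)
    stop("histogram must have 256 bins", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  if (n <= 0) stop("histogram is empty", call. = FALSE)
  structure(list(counts = as.integer(counts), probs = counts / n,
                 levels = 256L),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  occ <- which(x$counts > 0L) - 1L
  cat(sprintf("<gray_histogram: %d pixels, %d occupied bins [%d, %d]>\n",
              sum(x$counts), length(occ), min(occ), max(occ)))
  invisible(x)
}

#' Build the normalized histogram of an image
#'
#' Bin `m` collects pixels with `round(p * 255) == m`; counts sum to the
#' pixel count and probabilities sum to one.
#'
#' @param img a [gray_image()] or numeric matrix in `[0, 1]`.
#' @return A [gray_histogram()].
#' @examples
#' h <- compute_histogram(gray_image(matrix(0.5, 4, 4)))
#' h$counts[129]  # level 128, 1-based indexing
#' @export
compute_histogram <- function(img) {
  q <- quantize(img, 256L)
  gray_histogram(tabulate(as.vector(q) + 1L, nbins = 256L))
}

as_histogram <- function(x) {
  if (inherits(x, "gray_histogram")) return(x)
  if (is_gray_image(x) || is.matrix(x)) return(compute_histogram(x))
  if (is.numeric(x) && length(x) == 256L) {
    # accept a bare probability vector (scaled to pseudo-counts)
    if (abs(sum(x) - 1) < 1e-9 && !all(x == round(x)))
      return(structure(list(counts = NA_integer_, probs = x, levels = 256L),
                       class = "gray_histogram"))
    return(gray_histogram(x))
  }
  stop("cannot interpret input as a histogram", call. = FALSE)
}
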
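#' Disk structuring element
#'
#' Boolean footprint on the centered `(2r+1) x (2r+1)` grid with
#' `footprint[i, j]` true iff `i^2 + j^2 <= r^2` (offsets from the center).
#'
#' @param radius non-negative radius in pixels; radius 0 is a single pixel.
#' @return An object of class `structuring_element` with fields `radius` and
#'   `footprint`.
#' @export
disk_element <- function(radius) {
  radius <- as.numeric(radius)
  if (length(radius) != 1L || is.na(radius) || radius < 0)
    stop("'radius' must be a non-negative number", call. = FALSE)
  r <- floor(radius)
  off <- seq.int(-r, r)
  fp <- outer(off, off, function(i, j) i^2 + j^2 <= radius^2)
  structure(list(radius = radius, footprint = fp),
            class = "structuring_element")
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("<structuring_element disk r=%g: %dx%d, %d px>\n",
              x$radius, nrow(x$footprint), ncol(x$footprint),
              sum(x$footprint)))
  invisible(x)
}

# neighborhood counts of a binary field under a centered footprint, with
# zeros outside the canvas, via FFT (footprints are centrally symmetric, so
# correlation equals convolution)
neighbor_counts <- function(px, fp) {
  h <- nrow(px); w <- ncol(px)
  kh <- nrow(fp); kw <- ncol(fp)
  n1 <- h + kh - 1L; n2 <- w + kw - 1L
  A <- matrix(0, n1, n2); A[1:h, 1:w] <- px
  B <- matrix(0, n1, n2); B[1:kh, 1:kw] <- fp
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) /
    (n1 * n2)
  r1 <- (kh - 1L) / 2L; r2 <- (kw - 1L) / 2L
  round(conv[(r1 + 1L):(r1 + h), (r2 + 1L):(r2 + w)])
}

#' Binary erosion
#'
#' A pixel survives iff every true offset of the element lies on foreground;
#' pixels outside the canvas count as background.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param elem a [structuring_element()].
#' @return A [binary_mask()].
#' @export
erode_mask <- function(mask, elem) {
  px <- mask_matrix(mask)
  cnt <- neighbor_counts(px, elem$footprint)
  binary_mask(cnt >= sum(elem$footprint),
              role = if (inherits(mask, "binary_mask")) mask$role
                     else "segmentation")
}

#' Binary dilation
#'
#' A pixel becomes foreground iff the element centered there touches any
#' foreground pixel; outside the canvas is background.
#'
#' @inheritParams erode_mask
#' @return A [binary_mask()].
#' @export
dilate_mask <- function(mask, elem) {
  px <- mask_matrix(mask)
  cnt <- neighbor_counts(px, elem$footprint)
  binary_mask(cnt >= 1,
              role = if (inherits(mask, "binary_mask")) mask$role
                     else "segmentation")
}

#' Morphological refinement of a raw threshold mask
#'
#' Default is the opening (erosion followed by dilation with the same disk),
#' which removes any foreground feature that cannot contain a translate of
#' the element while preserving the shape of larger objects. A closing
#' (dilation then erosion) is available behind `morph = "closing"`. Optional
#' hole filling and largest-component selection are off by default.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param elem a [structuring_element()]; default disk of radius 10.
#' @param morph `"opening"` (default) or `"closing"`.
#' @param fill_holes fill background cavities not connected to the border.
#' @param largest_component keep only the largest 4-connected foreground
#'   component.
#' @return A [binary_mask()].
#' @export
refine_mask <- function(mask, elem = disk_element(10),
                        morph = c("opening", "closing"),
                        fill_holes = FALSE, largest_component = FALSE) {
  morph <- match.arg(morph)
  px <- mask_matrix(mask)
  if (nrow(elem$footprint) > nrow(px) || ncol(elem$footprint) > ncol(px)) {
    warning("structuring element larger than image; returning empty mask",
            call. = FALSE)
    return(binary_mask(matrix(FALSE, nrow(px), ncol(px))))
  }
  out <- if (morph == "opening") {
    dilate_mask(erode_mask(px, elem), elem)
  } else {
    erode_mask(dilate_mask(px, elem), elem)
  }
  if (fill_holes) out <- binary_mask(fill_holes_px(out$pixels), out$role)
  if (largest_component)
    out <- binary_mask(largest_component_px(out$pixels), out$role)
  out
}

# 4-connected propagation of a seed set within a region, by iterated
# cross-dilation; both arguments logical matrices
propagate <- function(seed, region) {
  cur <- seed & region
  repeat {
    h <- nrow(cur); w <- ncol(cur)
    grown <- cur
    grown[-1, ] <- grown[-1, ] | cur[-h, ]
    grown[-h, ] <- grown[-h, ] | cur[-1, ]
    grown[, -1] <- grown[, -1] | cur[, -w]
    grown[, -w] <- grown[, -w] | cur[, -1]
    grown <- grown & region
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

fill_holes_px <- function(px) {
  bg <- !px
  seed <- matrix(FALSE, nrow(px), ncol(px))
  seed[1, ] <- TRUE; seed[nrow(px), ] <- TRUE
  seed[, 1] <- TRUE; seed[, ncol(px)] <- TRUE
  outside <- propagate(seed & bg, bg)
  px | (bg & !outside)
}

largest_component_px <- function(px) {
  remaining <- px
  best <- matrix(FALSE, nrow(px), ncol(px))
  while (any(remaining)) {
    first <- which(remaining)[1]
    seed <- matrix(FALSE, nrow(px), ncol(px))
    seed[first] <- TRUE
    comp <- propagate(seed, remaining)
    if (sum(comp) > sum(best)) best <- comp
    remaining <- remaining & !comp
  }
  best
}
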
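#' Grayscale image container
#'
#' A `gray_image` stores a 2-D intensity field as a numeric matrix with all
#' values in `[0, 1]`, together with the number of gray levels `L` used by the
#' quantized view (256 throughout this package, indexed 0...L-1). All
#' histogram and threshold arithmetic operates on the quantized view
#' `round(pixel * (L - 1))`.
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`.
#' @param levels number of gray levels of the quantized view (default 256).
#' @return An object of class `gray_image` with fields `pixels` and `levels`.
#' @examples
#' img <- gray_image(matrix(seq(0, 1, length.out = 16), 4, 4))
#' dim(img)
#' @export
gray_image <- function(pixels, levels = 256L) {
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one pixel", call. = FALSE)
  if (anyNA(pixels))
    stop("image contains missing values", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("intensities must lie in [0, 1]", call. = FALSE)
  levels <- as.integer(levels)
  if (levels < 2L) stop("'levels' must be >= 2", call. = FALSE)
  structure(list(pixels = pixels, levels = levels), class = "gray_image")
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d gray levels, range [%.3f, %.3f]>\n",
              nrow(x$pixels), ncol(x$pixels), x$levels,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @rdname gray_image
#' @param x object to test or coerce.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

#' @rdname gray_image
#' @export
as_gray_image <- function(x) {
  if (is_gray_image(x)) return(x)
  gray_image(x)
}

# pull out the pixel matrix from either a gray_image or a bare matrix
pixel_matrix <- function(img) {
  if (is_gray_image(img)) img$pixels else as_gray_image(img)$pixels
}

#' Quantized integer view of an image
#'
#' Maps intensities in `[0, 1]` onto integer gray levels `0 ... L-1` by
#' `round(p * (L - 1))` (round half away from zero, matching 8-bit export).
#'
#' @param img a [gray_image()] or numeric matrix in `[0, 1]`.
#' @param levels number of gray levels (defaults to the image's own).
#' @return Integer matrix of the same dimensions with values in `0 ... L-1`.
#' @export
quantize <- function(img, levels = NULL) {
  g <- as_gray_image(img)
  L <- if (is.null(levels)) g$levels else as.integer(levels)
  q <- floor(g$pixels * (L - 1L) + 0.5)
  storage.mode(q) <- "integer"
  q
}

#' Binary mask container
#'
#' A `binary_mask` is a logical matrix marking foreground pixels, used both
#' for segmentations and for ground-truth lesion masks.
#'
#' @param pixels logical (or 0/1 numeric) matrix.
#' @param role one of `"segmentation"` or `"truth"`; informational only.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, role = c("segmentation", "truth")) {
  role <- match.arg(role)
  if (is.numeric(pixels)) {
    if (!all(pixels %in% c(0, 1)))
      stop("numeric mask must contain only 0 and 1", call. = FALSE)
    pixels <- pixels > 0
  }
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("'pixels' must be a logical matrix", call. = FALSE)
  structure(list(pixels = pixels, role = role), class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$pixels)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d (%s), %d foreground px>\n",
              nrow(x$pixels), ncol(x$pixels), x$role, sum(x$pixels)))
  invisible(x)
}

mask_matrix <- function(m) {
  if (inherits(m, "binary_mask")) m$pixels
  else if (is.logical(m) && is.matrix(m)) m
  else binary_mask(m)$pixels
}

#' Read a grayscale image
#'
#' Reads a portable graymap (PGM) file, the plain-raster format this package
#' uses for slices and masks: ASCII `P2` and binary `P5`, 8- or 16-bit.
#' Intensities are rescaled to `[0, 1]` by dividing by the file's stated
#' maximum value.
#'
#' @param path path to a `.pgm` file.
#' @return A [gray_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image '%s': no such file", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5"))
    stop(sprintf("'%s' is not a PGM (P2/P5) image", path), call. = FALSE)

  # header tokens: width height maxval, '#' comments allowed
  tokens <- integer(0)
  buf <- character(0)
  in_comment <- FALSE
  while (length(tokens) < 3L) {
    ch <- readBin(con, "raw", 1L)
    if (length(ch) == 0L)
      stop(sprintf("'%s': truncated PGM header", path), call. = FALSE)
    ch <- rawToChar(ch)
    if (in_comment) {
      if (ch == "\n") in_comment <- FALSE
      next
    }
    if (ch == "#") { in_comment <- TRUE; next }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0L) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (w < 1L || h < 1L)
    stop(sprintf("'%s': zero-sized image", path), call. = FALSE)
  if (maxval < 1L || maxval > 65535L)
    stop(sprintf("'%s': unsupported maxval %d", path, maxval), call. = FALSE)

  n <- w * h
  if (magic == "P5") {
    if (maxval > 255L) {
      vals <- readBin(con, "integer", n, size = 2L, signed = FALSE,
                      endian = "big")
    } else {
      vals <- as.integer(readBin(con, "raw", n))
    }
    if (length(vals) < n)
      stop(sprintf("'%s': truncated pixel data", path), call. = FALSE)
  } else {
    rest <- rawToChar(readBin(con, "raw", file.info(path)$size))
    vals <- suppressWarnings(as.integer(strsplit(trimws(rest), "\\s+")[[1]]))
    if (length(vals) < n || anyNA(vals))
      stop(sprintf("'%s': truncated or malformed pixel data", path),
           call. = FALSE)
    vals <- vals[seq_len(n)]
  }
  # PGM is row-major, top row first
  px <- matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
  gray_image(px)
}

#' Write a grayscale image or mask
#'
#' Writes the 256-level quantized view as an 8-bit PGM. Masks are written
#' with values 0/255.
#'
#' @param img a [gray_image()], numeric matrix in `[0,1]`, or [binary_mask()].
#' @param path output path.
#' @param ascii write ASCII `P2` (default `FALSE`, i.e. binary `P5`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, ascii = FALSE) {
  if (inherits(img, "binary_mask")) {
    q <- ifelse(img$pixels, 255L, 0L)
  } else {
    q <- quantize(img, 256L)
  }
  h <- nrow(q); w <- ncol(q)
  vals <- as.integer(t(q))  # row-major
  if (ascii) {
    con <- file(path, "wb")
    writeLines(c("P2", paste(w, h), "255",
                 paste(vals, collapse = " ")), con)
    close(con)
  } else {
    con <- file(path, "wb")
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(vals), con)
    close(con)
  }
  invisible(path)
}

#' Read a binary mask
#'
#' Reads a PGM and thresholds it at half intensity: pixels above 0.5 are
#' foreground.
#'
#' @param path path to a mask PGM.
#' @return A [binary_mask()] with role `"truth"`.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  binary_mask(img$pixels > 0.5, role = "truth")
}
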
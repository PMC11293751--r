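#' Geometric augmentation configuration
#'
#' Defaults reproduce a ninefold corpus expansion (original plus eight
#' sampled transforms), with ranges symmetric about the identity: rotation
#' +/-15 degrees, translation +/-10 px, scale `[0.9, 1.1]`, shear +/-10
#' degrees, horizontal reflection with probability 0.5.
#'
#' @param replication_factor outputs per input, original included (>= 1).
#' @param rotation_range max absolute rotation, degrees.
#' @param translation_range max absolute translation, pixels (both axes).
#' @param scale_range length-2 numeric interval containing 1.
#' @param shear_range max absolute shear, degrees.
#' @param reflect allow horizontal reflection (sampled with probability 0.5).
#' @param seed integer RNG seed; equal seeds give identical corpora.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(replication_factor = 9L, rotation_range = 15,
                           translation_range = 10, scale_range = c(0.9, 1.1),
                           shear_range = 10, reflect = TRUE, seed = 17L) {
  replication_factor <- as.integer(replication_factor)
  if (is.na(replication_factor) || replication_factor < 1L)
    stop("'replication_factor' must be a positive integer", call. = FALSE)
  if (length(scale_range) != 2L || scale_range[1] > 1 || scale_range[2] < 1)
    stop("'scale_range' must be an interval containing 1", call. = FALSE)
  structure(list(replication_factor = replication_factor,
                 rotation_range = rotation_range,
                 translation_range = translation_range,
                 scale_range = scale_range, shear_range = shear_range,
                 reflect = reflect, seed = as.integer(seed)),
            class = "augment_config")
}

#' Sample one transform specification
#'
#' Draws rotation, translation, scale, shear and reflection uniformly from
#' the configured ranges using the current RNG stream.
#'
#' @param cfg an [augment_config()].
#' @return A named list usable by [apply_transform()].
#' @export
sample_transform <- function(cfg) {
  list(rotation = stats::runif(1, -cfg$rotation_range, cfg$rotation_range),
       translation = stats::runif(2, -cfg$translation_range,
                                  cfg$translation_range),
       scale = stats::runif(1, cfg$scale_range[1], cfg$scale_range[2]),
       shear = stats::runif(1, -cfg$shear_range, cfg$shear_range),
       reflect = cfg$reflect && stats::runif(1) < 0.5)
}

identity_transform <- function() {
  list(rotation = 0, translation = c(0, 0), scale = 1, shear = 0,
       reflect = FALSE)
}

# 2x2 linear part of the forward affine map (about the image center)
transform_matrix <- function(spec) {
  th <- spec$rotation * pi / 180
  sh <- tan(spec$shear * pi / 180)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, sh, 1), 2, 2)          # shear along x
  Z <- diag(c(spec$scale, spec$scale))
  Fm <- diag(c(if (isTRUE(spec$reflect)) -1 else 1, 1))
  R %*% S %*% Z %*% Fm
}

#' Apply an affine transform to an image
#'
#' The forward map rotates/shears/scales/reflects about the image center and
#' then translates; output pixels are resampled by inverse mapping with
#' bilinear interpolation and zero fill outside the canvas. Output dimensions
#' equal input dimensions and the class label is unaffected.
#'
#' @param img a [gray_image()] or numeric matrix, or a [binary_mask()]
#'   (resampled and re-thresholded at 0.5).
#' @param spec transform parameters as from [sample_transform()]: fields
#'   `rotation` (deg), `translation` (length-2, px), `scale`, `shear` (deg),
#'   `reflect` (logical).
#' @param cfg optional [augment_config()]; when given, `spec` is validated
#'   against its ranges.
#' @return Same type as `img`.
#' @export
apply_transform <- function(img, spec, cfg = NULL) {
  if (!is.null(cfg)) {
    ok <- abs(spec$rotation) <= cfg$rotation_range + 1e-9 &&
      all(abs(spec$translation) <= cfg$translation_range + 1e-9) &&
      spec$scale >= cfg$scale_range[1] - 1e-9 &&
      spec$scale <= cfg$scale_range[2] + 1e-9 &&
      abs(spec$shear) <= cfg$shear_range + 1e-9
    if (!ok)
      stop("transform parameters outside configured ranges", call. = FALSE)
  }
  is_mask <- inherits(img, "binary_mask")
  p <- if (is_mask) (img$pixels + 0) else pixel_matrix(img)
  h <- nrow(p); w <- ncol(p)
  A <- transform_matrix(spec)
  Ainv <- solve(A)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  # output grid (x = col, y = row)
  gx <- rep(seq_len(w), each = h)
  gy <- rep(seq_len(h), times = w)
  ux <- gx - cx - spec$translation[1]
  uy <- gy - cy - spec$translation[2]
  sx <- Ainv[1, 1] * ux + Ainv[1, 2] * uy + cx
  sy <- Ainv[2, 1] * ux + Ainv[2, 2] * uy + cy
  # bilinear sample with zero outside [1, w] x [1, h]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- numeric(h * w)
  at <- function(xi, yi) {
    inside <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    v <- numeric(length(xi))
    idx <- (pmin(pmax(xi, 1L), w) - 1L) * h + pmin(pmax(yi, 1L), h)
    v[inside] <- p[idx[inside]]
    v
  }
  val <- at(x0, y0) * (1 - fx) * (1 - fy) +
    at(x0 + 1, y0) * fx * (1 - fy) +
    at(x0, y0 + 1) * (1 - fx) * fy +
    at(x0 + 1, y0 + 1) * fx * fy
  out <- matrix(val, h, w)
  if (is_mask) return(binary_mask(out > 0.5, role = img$role))
  out[out < 0] <- 0; out[out > 1] <- 1
  if (is_gray_image(img)) gray_image(out, levels = img$levels) else out
}

#' Augment a labeled dataset by a fixed replication factor
#'
#' Each input contributes its unmodified original plus
#' `replication_factor - 1` sampled geometric transforms; labels (and masks,
#' when present) are carried along, so per-class counts scale exactly by the
#' factor. Deterministic under the configured seed. With the defaults, the
#' reference 264-slice corpus (194 abnormal / 70 normal) grows to 2376
#' (1746 / 630).
#'
#' @param ds an [mri_dataset()], non-empty.
#' @param cfg an [augment_config()].
#' @param out_dir optional directory: images (and masks) are written as PGM
#'   with a `manifest.csv`, and the returned dataset references files rather
#'   than holding them in memory.
#' @return An [mri_dataset()] of size `replication_factor * length(ds)`.
#' @export
augment_dataset <- function(ds, cfg = augment_config(), out_dir = NULL) {
  if (length(ds) == 0L) stop("dataset is empty", call. = FALSE)
  n <- length(ds)
  f <- cfg$replication_factor
  with_seed(cfg$seed, {
    labels <- character(n * f)
    images <- if (is.null(out_dir)) vector("list", n * f) else NULL
    paths <- if (is.null(out_dir)) NULL else character(n * f)
    has_masks <- !is.null(ds$masks)
    masks <- if (has_masks) vector("list", n * f) else NULL
    if (!is.null(out_dir))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    k <- 0L
    for (i in seq_len(n)) {
      img <- dataset_image(ds, i)
      msk <- if (has_masks) dataset_mask(ds, i) else NULL
      for (j in seq_len(f)) {
        k <- k + 1L
        spec <- if (j == 1L) identity_transform() else sample_transform(cfg)
        out <- if (j == 1L) img else apply_transform(img, spec, cfg)
        labels[k] <- ds$labels[i]
        mout <- NULL
        if (has_masks && !is.null(msk))
          mout <- if (j == 1L) msk else apply_transform(msk, spec, cfg)
        if (is.null(out_dir)) {
          images[[k]] <- out
          if (has_masks) masks[[k]] <- if (is.null(mout)) NA else mout
        } else {
          pth <- file.path(out_dir, sprintf("img_%05d.pgm", k))
          write_image(out, pth)
          paths[k] <- pth
          if (has_masks) {
            if (is.null(mout)) masks[[k]] <- NA
            else {
              mp <- file.path(out_dir, sprintf("img_%05d_mask.pgm", k))
              write_image(mout, mp)
              masks[[k]] <- mp
            }
          }
        }
      }
    }
    aug <- mri_dataset(labels, images = images, paths = paths, masks = masks)
    if (!is.null(out_dir)) write_manifest(aug, file.path(out_dir, "manifest.csv"))
    aug
  })
}
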
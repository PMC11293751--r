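#' Phantom specification
#'
#' Describes a 256 x 256 T2-like axial slice: an elliptical head on dark
#' background, a brighter parenchyma stratum, two hyperintense
#' ventricle-like crescents, and 0-3 hyperintense circular tumors with
#' exactly known masks. Tumor intensity must exceed every tissue mean
#' (T2-like hyperintensity) and tumor radii must be at least 13 px so that
#' a true lesion cannot be erased by the default radius-10 opening.
#'
#' @param tumors list of tumors, each `list(center = c(row, col), radius,
#'   intensity)`; may be empty.
#' @param head list with `center = c(row, col)` and `axes = c(row_semi,
#'   col_semi)` of the head ellipse.
#' @param tissues list of strata `list(mean, sd)` named `background`,
#'   `parenchyma`, `csf`.
#' @param tumor_sd Gaussian noise SD inside tumors.
#' @param bias_amplitude amplitude of the smooth multiplicative bias field
#'   (0 disables).
#' @param ventricles logical: draw the two ventricle crescents.
#' @param boundary_noise logical: perturb tumor boundaries with a
#'   low-frequency radial ripple (default off; masks stay exact).
#' @param seed integer seed; identical specs give identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tumors = list(),
                         head = list(center = c(128.5, 128.5),
                                     axes = c(118, 100)),
                         tissues = list(background = list(mean = 0.03, sd = 0.012),
                                        parenchyma = list(mean = 0.50, sd = 0.030),
                                        csf = list(mean = 0.68, sd = 0.030)),
                         tumor_sd = 0.030,
                         bias_amplitude = 0.05,
                         ventricles = TRUE,
                         boundary_noise = FALSE,
                         seed = 1L) {
  tis_means <- vapply(tissues, function(t) t$mean, numeric(1))
  for (tu in tumors) {
    if (tu$radius < 13)
      stop("tumor radius must be >= 13 px", call. = FALSE)
    if (tu$intensity <= max(tis_means))
      stop("tumor intensity must exceed all tissue means", call. = FALSE)
    # fully inside the head ellipse
    dz <- (tu$center - head$center) / (head$axes - tu$radius)
    if (any(head$axes - tu$radius <= 0) || sum(dz^2) > 1)
      stop("tumor lies (partly) outside the head ellipse", call. = FALSE)
  }
  structure(list(tumors = tumors, head = head, tissues = tissues,
                 tumor_sd = tumor_sd,
                 bias_amplitude = bias_amplitude,
                 ventricles = ventricles, boundary_noise = boundary_noise,
                 seed = as.integer(seed), size = c(256L, 256L)),
            class = "phantom_spec")
}

# logical ellipse on the standard 256x256 grid
ellipse_region <- function(center, axes, size = c(256L, 256L)) {
  rows <- matrix(seq_len(size[1]), size[1], size[2])
  cols <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  ((rows - center[1]) / axes[1])^2 + ((cols - center[2]) / axes[2])^2 <= 1
}

disk_region <- function(center, radius, size = c(256L, 256L),
                        ripple = NULL) {
  rows <- matrix(seq_len(size[1]), size[1], size[2])
  cols <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  dr <- rows - center[1]; dc <- cols - center[2]
  r_eff <- radius
  if (!is.null(ripple)) {
    th <- atan2(dr, dc)
    r_eff <- radius * (1 + ripple$amp * sin(ripple$k * th + ripple$phase))
  }
  dr^2 + dc^2 <= r_eff^2
}

#' Generate one synthetic phantom
#'
#' Renders the spec deterministically (per-spec seed): tissue means plus an
#' optional smooth multiplicative bias field, additive Gaussian noise per
#' stratum, clipped to `[0, 1]`. The ground-truth mask is the exact union of
#' the tumor disks and the label is `"abnormal"` iff at least one tumor is
#' present.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `image` ([gray_image()]), `mask`
#'   ([binary_mask()] with role `"truth"`) and `label`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    sz <- spec$size
    head <- ellipse_region(spec$head$center, spec$head$axes, sz)
    field <- matrix(spec$tissues$background$mean, sz[1], sz[2])
    sdmap <- matrix(spec$tissues$background$sd, sz[1], sz[2])
    field[head] <- spec$tissues$parenchyma$mean
    sdmap[head] <- spec$tissues$parenchyma$sd
    if (isTRUE(spec$ventricles)) {
      for (s in c(-1, 1)) {
        v <- ellipse_region(spec$head$center + c(-6, s * 24), c(26, 9), sz)
        v <- v & head
        field[v] <- spec$tissues$csf$mean
        sdmap[v] <- spec$tissues$csf$sd
      }
    }
    mask <- matrix(FALSE, sz[1], sz[2])
    for (tu in spec$tumors) {
      ripple <- NULL
      if (isTRUE(spec$boundary_noise))
        ripple <- list(amp = 0.08, k = sample(3:6, 1),
                       phase = stats::runif(1, 0, 2 * pi))
      d <- disk_region(tu$center, tu$radius, sz, ripple)
      field[d] <- tu$intensity
      sdmap[d] <- spec$tumor_sd
      mask <- mask | d
    }
    if (spec$bias_amplitude > 0) {
      rows <- matrix(seq_len(sz[1]) / sz[1], sz[1], sz[2])
      cols <- matrix(seq_len(sz[2]) / sz[2], sz[1], sz[2], byrow = TRUE)
      bias <- 1 + spec$bias_amplitude *
        sin(pi * rows + stats::runif(1, 0, pi)) *
        cos(pi * cols + stats::runif(1, 0, pi))
      field <- field * bias
    }
    noisy <- field + stats::rnorm(length(field), 0, as.vector(sdmap))
    noisy[noisy < 0] <- 0; noisy[noisy > 1] <- 1
    list(image = gray_image(matrix(noisy, sz[1], sz[2])),
         mask = binary_mask(mask, role = "truth"),
         label = if (length(spec$tumors) > 0) "abnormal" else "normal")
  })
}

# sample a valid random phantom spec (tumors non-overlapping, inside head)
random_phantom_spec <- function(n_tumors, seed, radius_range = c(14, 28),
                                ...) {
  with_seed(seed, {
    head <- list(center = c(128.5, 128.5),
                 axes = c(stats::runif(1, 110, 124),
                          stats::runif(1, 92, 106)))
    tumors <- list()
    tries <- 0L
    while (length(tumors) < n_tumors && tries < 500L) {
      tries <- tries + 1L
      r <- stats::runif(1, radius_range[1], radius_range[2])
      margin <- head$axes - r - 6
      ctr <- head$center + c(stats::runif(1, -1, 1) * margin[1],
                             stats::runif(1, -1, 1) * margin[2]) *
        stats::runif(1, 0, 0.85)
      if (sum(((ctr - head$center) / margin)^2) > 1) next
      clash <- any(vapply(tumors, function(t)
        sqrt(sum((t$center - ctr)^2)) < t$radius + r + 6, logical(1)))
      # keep lesions off the ventricle midline strip
      if (!clash)
        tumors[[length(tumors) + 1L]] <-
          list(center = ctr, radius = r,
               intensity = stats::runif(1, 0.90, 0.95))
    }
    phantom_spec(tumors = tumors, head = head,
                 seed = sample.int(.Machine$integer.max, 1L), ...)
  })
}

#' Generate a labeled synthetic dataset
#'
#' Randomized phantom specs per item: abnormal slices carry 1-3 tumors,
#' normal slices none. Defaults mirror the 194 abnormal / 70 normal
#' reference corpus. Deterministic under the seed.
#'
#' @param n_abnormal,n_normal item counts (non-negative).
#' @param seed integer RNG seed.
#' @param out_dir optional directory: images and masks are written as PGM
#'   with a `manifest.csv`; otherwise the dataset is kept in memory.
#' @param radius_range tumor radius range in pixels (min must be >= 13).
#' @return An [mri_dataset()] with ground-truth masks.
#' @export
make_dataset <- function(n_abnormal = 194L, n_normal = 70L, seed = 17L,
                         out_dir = NULL, radius_range = c(14, 28)) {
  n_abnormal <- as.integer(n_abnormal); n_normal <- as.integer(n_normal)
  stopifnot(n_abnormal >= 0L, n_normal >= 0L, radius_range[1] >= 13)
  n <- n_abnormal + n_normal
  with_seed(seed, {
    n_tum <- c(sample(1:3, n_abnormal, replace = TRUE,
                      prob = c(0.6, 0.25, 0.15)),
               rep(0L, n_normal))
    item_seeds <- sample.int(.Machine$integer.max, n)
    ord <- sample.int(n)  # shuffle class order
    n_tum <- n_tum[ord]; item_seeds <- item_seeds[ord]
    labels <- ifelse(n_tum > 0, "abnormal", "normal")
    if (!is.null(out_dir))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    images <- if (is.null(out_dir)) vector("list", n) else NULL
    paths <- if (is.null(out_dir)) NULL else character(n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      ph <- make_phantom(random_phantom_spec(n_tum[i], item_seeds[i],
                                             radius_range))
      if (is.null(out_dir)) {
        images[[i]] <- ph$image
        masks[[i]] <- ph$mask
      } else {
        pth <- file.path(out_dir, sprintf("phantom_%04d.pgm", i))
        write_image(ph$image, pth)
        paths[i] <- pth
        mp <- file.path(out_dir, sprintf("phantom_%04d_mask.pgm", i))
        write_image(ph$mask, mp)
        masks[[i]] <- mp
      }
    }
    ds <- mri_dataset(labels, images = images, paths = paths, masks = masks)
    if (!is.null(out_dir))
      write_manifest(ds, file.path(out_dir, "manifest.csv"))
    ds
  })
}

#' Named histogram fixtures for the thresholding oracles
#'
#' Deterministic sparse histograms: `two_spike` puts half the mass at levels
#' 50 and 200; `trimodal` spreads mass over three narrow modes at levels 40,
#' 120 and 200 (15 occupied bins); `uniform8`/`uniform16` spread mass
#' equally over 8/16 evenly spaced levels; `example8` is the 8-level vector
#' (.1, .2, .1, .1, .15, .15, .1, .1) on levels 0-7.
#'
#' @param kind one of `"two_spike"`, `"trimodal"`, `"uniform8"`,
#'   `"uniform16"`, `"example8"`.
#' @return A [gray_histogram()].
#' @export
make_histogram_fixture <- function(kind = c("two_spike", "trimodal",
                                            "uniform8", "uniform16",
                                            "example8")) {
  kind <- match.arg(kind)
  counts <- integer(256L)
  if (kind == "two_spike") {
    counts[c(50, 200) + 1L] <- 500L
  } else if (kind == "trimodal") {
    modes <- list(c(40, 30L), c(120, 50L), c(200, 20L))
    for (md in modes) {
      lv <- md[1] + (-2:2)
      counts[lv + 1L] <- counts[lv + 1L] + md[2] * c(1L, 3L, 6L, 3L, 1L)
    }
  } else if (kind == "uniform8") {
    counts[round(seq(0, 255, length.out = 8)) + 1L] <- 100L
  } else if (kind == "uniform16") {
    counts[round(seq(0, 255, length.out = 16)) + 1L] <- 100L
  } else {
    counts[1:8] <- as.integer(c(10, 20, 10, 10, 15, 15, 10, 10))
  }
  gray_histogram(counts)
}
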
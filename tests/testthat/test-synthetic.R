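test_that("phantoms honor spec, determinism and intensity ordering", {
  spec <- phantom_spec(tumors = list(list(center = c(110, 128), radius = 20,
                                          intensity = 0.92)), seed = 3)
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask$pixels, b$mask$pixels)
  expect_identical(a$label, "abnormal")
  expect_true(all(a$image$pixels >= 0 & a$image$pixels <= 1))
  expect_identical(sum(a$mask$pixels),
                   sum(mriseg:::disk_region(c(110, 128), 20)))

  # tumor mean well above the head interior outside the lesion
  head <- mriseg:::ellipse_region(spec$head$center, spec$head$axes)
  inside <- mean(a$image$pixels[a$mask$pixels])
  outside <- mean(a$image$pixels[head & !a$mask$pixels])
  expect_gt(inside - outside, 0.2)

  none <- make_phantom(phantom_spec(seed = 4))
  expect_identical(none$label, "normal")
  expect_false(any(none$mask$pixels))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(tumors = list(list(center = c(128, 128),
                                               radius = 5,
                                               intensity = 0.95))),
               ">= 13")
  expect_error(phantom_spec(tumors = list(list(center = c(10, 10),
                                               radius = 20,
                                               intensity = 0.95))),
               "outside the head")
  expect_error(phantom_spec(tumors = list(list(center = c(128, 128),
                                               radius = 20,
                                               intensity = 0.4))),
               "exceed all tissue means")
})

test_that("make_dataset delivers exact class counts and reproducibility", {
  ds <- make_dataset(7, 3, seed = 21)
  expect_identical(dataset_counts(ds), c(abnormal = 7L, normal = 3L))
  ds2 <- make_dataset(7, 3, seed = 21)
  expect_identical(dataset_image(ds, 5)$pixels, dataset_image(ds2, 5)$pixels)
  expect_true(all(vapply(which(ds$labels == "normal"), function(i)
    !any(dataset_mask(ds, i)$pixels), logical(1))))
  all_norm <- make_dataset(0, 5, seed = 1)
  expect_true(all(all_norm$labels == "normal"))
})

test_that("dataset written to disk round-trips through its manifest", {
  dir <- tempfile()
  ds <- make_dataset(2, 1, seed = 8, out_dir = dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_identical(length(man), 3L)
  expect_identical(dataset_counts(man), c(abnormal = 2L, normal = 1L))
  expect_identical(quantize(dataset_image(man, 1)),
                   quantize(dataset_image(ds, 1)))
  m <- dataset_mask(man, 1)
  expect_s3_class(m, "binary_mask")
  unlink(dir, recursive = TRUE)
})

test_that("histogram fixtures are the documented distributions", {
  ts <- make_histogram_fixture("two_spike")
  expect_equal(ts$probs[c(51, 201)], c(0.5, 0.5))
  expect_identical(sum(ts$probs > 0), 2L)

  u8 <- make_histogram_fixture("uniform8")
  expect_identical(sum(u8$probs > 0), 8L)
  expect_true(all(abs(u8$probs[u8$probs > 0] - 0.125) < 1e-12))

  u16 <- make_histogram_fixture("uniform16")
  expect_identical(sum(u16$probs > 0), 16L)

  tri <- make_histogram_fixture("trimodal")
  expect_lte(sum(tri$probs > 0), 16L)
  occ <- which(tri$probs > 0) - 1L
  # modes sit at the stated levels
  loc <- sapply(c(40, 120, 200), function(m)
    occ[which.max(tri$probs[occ + 1][abs(occ - m) <= 2])])
  expect_identical(as.integer(c(40, 120, 200)),
                   as.integer(sapply(c(40, 120, 200), function(m) {
                     w <- which(abs((0:255) - m) <= 2)
                     w[which.max(tri$probs[w])] - 1L
                   })))
  expect_error(make_histogram_fixture("nope"))
})

test_that("abnormal phantoms survive the default segmentation path", {
  # lesions are built larger than the opening radius, so DSC stays positive
  for (s in 1:3) {
    ph <- make_phantom(mriseg:::random_phantom_spec(1, seed = 400 + s))
    res <- segment_image(ph$image, tsallis_params(0.5, 6),
                         de_config(D = 6, seed = s))
    expect_gt(dice(res$refined, ph$mask), 0)
  }
})
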
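test_that("gray_image validates its invariants", {
  expect_error(gray_image(matrix(1.2, 2, 2)), "\\[0, 1\\]")
  expect_error(gray_image(matrix(numeric(0), 0, 0)), "at least one pixel")
  img <- gray_image(matrix(c(0, 0.2, 0.4, 1), 2, 2))
  expect_identical(dim(img), c(2L, 2L))
  expect_equal(img$levels, 256L)
})

test_that("quantize maps [0,1] onto exact integer levels", {
  img <- gray_image(matrix(c(0, 0.2, 0.4, 1), 2, 2))
  expect_identical(as.vector(quantize(img)), c(0L, 51L, 102L, 255L))
  expect_identical(quantize(gray_image(matrix(0.5, 1, 1)))[1, 1], 128L)
})

test_that("PGM round trip preserves the quantized view exactly", {
  set.seed(42)
  img <- gray_image(matrix(runif(15 * 11), 15, 11))
  for (ascii in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".pgm")
    write_image(img, path, ascii = ascii)
    back <- read_image(path)
    expect_identical(quantize(back), quantize(img), info = paste("ascii:", ascii))
    unlink(path)
  }
})

test_that("read_image handles the documented value scale and errors", {
  path <- tempfile(fileext = ".pgm")
  writeLines(c("P2", "2 2", "255", "0 51", "102 255"), path)
  img <- read_image(path)
  expect_equal(as.vector(t(img$pixels)), c(0, 0.2, 0.4, 1))
  unlink(path)
  expect_error(read_image(tempfile()), "no such file")
  bad <- tempfile(fileext = ".pgm")
  writeLines(c("P2", "0 0", "255"), bad)
  expect_error(read_image(bad), "zero-sized")
  unlink(bad)
})

test_that("16-bit PGM input is rescaled by its maxval", {
  path <- tempfile(fileext = ".pgm")
  writeLines(c("P2", "2 1", "65535", "0 65535"), path)
  img <- read_image(path)
  expect_equal(as.vector(img$pixels), c(0, 1))
  unlink(path)
})

test_that("histogram counts conserve pixels and probabilities normalize", {
  img <- gray_image(matrix(0.5, 4, 4))
  h <- compute_histogram(img)
  expect_identical(h$counts[129], 16L)  # level 128
  expect_identical(sum(h$counts), 16L)
  expect_equal(sum(h$probs), 1)
  h2 <- compute_histogram(gray_image(matrix(c(0, 1), 1, 2)))
  expect_equal(h2$probs[c(1, 256)], c(0.5, 0.5))
  set.seed(7)
  for (i in 1:5) {
    img <- gray_image(matrix(runif(64), 8, 8))
    expect_identical(sum(compute_histogram(img)$counts), 64L)
  }
})

test_that("manifest round trip, counts, and label validation", {
  dir <- tempfile(); dir.create(dir)
  for (i in 1:3)
    write_image(gray_image(matrix(runif(16), 4, 4)),
                file.path(dir, sprintf("im%d.pgm", i)))
  man <- file.path(dir, "m.csv")
  writeLines(c("path,label", "im1.pgm,abnormal", "im2.pgm,abnormal",
               "im3.pgm,normal"), man)
  ds <- read_manifest(man)
  expect_identical(dataset_counts(ds), c(abnormal = 2L, normal = 1L))
  expect_s3_class(dataset_image(ds, 1), "gray_image")

  empty <- file.path(dir, "e.csv")
  writeLines("path,label", empty)
  expect_identical(length(read_manifest(empty)), 0L)

  bad <- file.path(dir, "b.csv")
  writeLines(c("path,label", "im1.pgm,tumour"), bad)
  expect_error(read_manifest(bad), "row 1")
  unlink(dir, recursive = TRUE)
})

test_that("write_report emits twin CSV and JSON", {
  df <- data.frame(image = "1", DSC = 92.8)
  stem <- tempfile()
  paths <- write_report(df, stem)
  expect_true(all(file.exists(paths)))
  expect_equal(jsonlite::read_json(paths[["json"]],
                                   simplifyVector = TRUE)$DSC, 92.8)
  unlink(paths)
})
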
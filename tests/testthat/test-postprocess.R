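test_that("disk footprints enumerate i^2 + j^2 <= r^2 exactly", {
  expect_identical(disk_element(0)$footprint, matrix(TRUE, 1, 1))
  d1 <- disk_element(1)$footprint
  expect_identical(sum(d1), 5L)
  expect_true(d1[2, 2] && d1[1, 2] && d1[2, 1] && !d1[1, 1])
  expect_identical(sum(disk_element(2)$footprint), 13L)
  expect_error(disk_element(-1), "non-negative")
})

test_that("opening matches the brute-force oracle pixel-exactly", {
  elem <- disk_element(10)
  # 60x60 solid square: corners rounded, interior preserved
  sq <- matrix(FALSE, 80, 80); sq[11:70, 11:70] <- TRUE
  got <- refine_mask(sq, elem)$pixels
  want <- brute_opening(sq, elem$footprint)
  expect_identical(got, want)
  expect_true(all(got[31:50, 31:50]))
  # 5x5 speck vanishes entirely
  speck <- matrix(FALSE, 40, 40); speck[18:22, 18:22] <- TRUE
  expect_false(any(refine_mask(speck, elem)$pixels))
  # empty in, empty out
  expect_false(any(refine_mask(matrix(FALSE, 30, 30), elem)$pixels))
})

test_that("erosion and dilation individually match their oracles", {
  set.seed(10)
  elem <- disk_element(3)
  for (i in 1:5) {
    px <- random_mask(32L, 32L)
    expect_identical(erode_mask(px, elem)$pixels,
                     brute_erode(px, elem$footprint))
    expect_identical(dilate_mask(px, elem)$pixels,
                     brute_dilate(px, elem$footprint))
  }
})

test_that("opening is anti-extensive, idempotent and monotone", {
  set.seed(11)
  elem <- disk_element(2)
  for (i in 1:100) {
    px <- random_mask()
    op <- refine_mask(px, elem)$pixels
    expect_true(all(op <= px))                    # anti-extensive
    expect_identical(refine_mask(op, elem)$pixels, op)  # idempotent
  }
  for (i in 1:10) {
    a <- random_mask()
    b <- a | random_mask()
    expect_true(all(refine_mask(a, elem)$pixels <= refine_mask(b, elem)$pixels))
  }
})

test_that("opening is translation-equivariant on interior masks", {
  set.seed(12)
  elem <- disk_element(2)
  core <- matrix(FALSE, 40, 40)
  core[15:24, 15:24] <- random_mask(10L, 10L)
  shifted <- matrix(FALSE, 40, 40)
  shifted[18:27, 12:21] <- core[15:24, 15:24]
  a <- refine_mask(core, elem)$pixels
  b <- refine_mask(shifted, elem)$pixels
  expect_identical(b[18:27, 12:21], a[15:24, 15:24])
})

test_that("oversized element yields an all-false mask with a warning", {
  expect_warning(out <- refine_mask(matrix(TRUE, 5, 5), disk_element(10)),
                 "larger than image")
  expect_false(any(out$pixels))
})

test_that("closing, hole filling and largest-component flags behave", {
  ring <- matrix(FALSE, 30, 30)
  for (i in 1:30) for (j in 1:30) {
    d2 <- (i - 15.5)^2 + (j - 15.5)^2
    if (d2 <= 100 && d2 >= 36) ring[i, j] <- TRUE
  }
  filled <- refine_mask(ring, disk_element(0), fill_holes = TRUE)$pixels
  expect_true(all(filled[(row(filled) - 15.5)^2 + (col(filled) - 15.5)^2 <= 100]))
  two <- matrix(FALSE, 30, 30)
  two[2:4, 2:4] <- TRUE; two[10:25, 10:25] <- TRUE
  big <- refine_mask(two, disk_element(0), largest_component = TRUE)$pixels
  expect_false(any(big[2:4, 2:4])); expect_true(all(big[10:25, 10:25]))
  cl <- refine_mask(two, disk_element(1), morph = "closing")$pixels
  expect_true(all(cl[10:25, 10:25]))
})
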
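test_that("confusion metrics reproduce hand-computed values", {
  m <- confusion_metrics(confusion_counts(TP = 9, FN = 1, TN = 8, FP = 2))
  expect_equal(m$TPR, 0.9)
  expect_equal(m$TNR, 0.8)
  expect_equal(m$AUC, 0.85)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$PPV, 9 / 11)
  expect_equal(m$f_score, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9))

  perfect <- confusion_metrics(confusion_counts(TP = 5, TN = 7, FP = 0,
                                                FN = 0))
  expect_true(all(unlist(perfect) == 1))

  onesided <- suppressWarnings(
    confusion_metrics(confusion_counts(TP = 0, FN = 3, TN = 4, FP = 0)))
  expect_equal(onesided$TPR, 0)
  expect_equal(onesided$TNR, 1)
  expect_equal(onesided$AUC, 0.5)
})

test_that("zero denominators propagate as NA with a warning", {
  w <- capture_warnings(
    m <- confusion_metrics(confusion_counts(TP = 0, TN = 5, FP = 0,
                                            FN = 0)))
  expect_true(any(grepl("TPR", w)))
  expect_true(any(grepl("PPV", w)))
  expect_true(is.na(m$TPR))
  expect_false(is.na(m$TNR))
})

test_that("dice handles the documented special cases", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dice(a, matrix(TRUE, 3, 3)), "dimensions")
  # |T| = 100, |T_G| = 80, overlap 60 -> 0.6667
  t1 <- matrix(FALSE, 20, 20); t1[1:10, 1:10] <- TRUE
  t2 <- matrix(FALSE, 20, 20); t2[1:10, 5:12] <- TRUE
  expect_identical(c(sum(t1), sum(t2), sum(t1 & t2)), c(100L, 80L, 60L))
  expect_equal(dice(t1, t2), 120 / 180)
})

test_that("pixel confusion partitions the frame and links to dice", {
  a <- matrix(TRUE, 4, 4)
  cc <- pixel_confusion(a, a)
  expect_identical(c(cc$TP, cc$TN, cc$FP, cc$FN), c(16L, 0L, 0L, 0L))

  seg <- matrix(FALSE, 6, 6)
  gt <- matrix(FALSE, 6, 6); gt[1:5, 1] <- TRUE
  cc <- pixel_confusion(seg, gt)
  expect_identical(c(cc$FN, cc$TN), c(5L, 31L))

  chk <- matrix((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2 == 0, 4, 4)
  cc <- pixel_confusion(chk, !chk)
  expect_identical(c(cc$TP, cc$TN, cc$FP, cc$FN), c(0L, 0L, 8L, 8L))

  set.seed(13)
  for (i in 1:100) {
    s <- random_mask(16L, 16L); g <- random_mask(16L, 16L)
    cc <- pixel_confusion(s, g)
    expect_identical(cc$TP + cc$TN + cc$FP + cc$FN, 256L)
    expect_equal(dice(s, g), 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN))
    expect_equal(dice(s, g), dice(g, s))
  }
})

test_that("segmentation report carries the expected columns and average", {
  set.seed(14)
  segs <- replicate(3, random_mask(12L, 12L), simplify = FALSE)
  gts <- replicate(3, random_mask(12L, 12L), simplify = FALSE)
  rep <- suppressWarnings(segmentation_report(segs, gts))
  expect_identical(names(rep),
                   c("image", "DSC", "PPV", "TPR", "TNR", "F_Score", "AUC",
                     "Accuracy"))
  expect_identical(rep$image[4], "Average")
  expect_equal(rep$DSC[4], mean(rep$DSC[1:3]))
})
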
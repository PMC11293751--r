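#' Confusion counts
#'
#' @param TP,TN,FP,FN non-negative integer counts; their total must be
#'   positive.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(v) <= 0) stop("total count must be positive", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TPR = TP/(TP+FN)`, specificity
#' `TNR = TN/(TN+FP)`, precision `PPV = TP/(TP+FP)`, `F = 2 PPV TPR /
#' (PPV + TPR)` and `AUC = (TPR + TNR)/2`. The AUC here is balanced
#' accuracy by definition, not a ROC integral. Metrics with a zero
#' denominator are reported as `NA` (never coerced to 0) with a warning
#' naming the offending denominator.
#'
#' @param counts a [confusion_counts()].
#' @return A named list of class `metrics_report` with fields `accuracy`,
#'   `TPR`, `TNR`, `PPV`, `f_score`, `AUC`, all fractions in `[0, 1]`.
#' @examples
#' confusion_metrics(confusion_counts(TP = 9, TN = 8, FP = 2, FN = 1))
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den, name) {
    if (den <= 0) {
      warning(sprintf("zero denominator for %s; reported as NA", name),
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  with(counts, {
    acc <- safe_div(TP + TN, TP + TN + FP + FN, "accuracy")
    tpr <- safe_div(TP, TP + FN, "TPR (TP+FN)")
    tnr <- safe_div(TN, TN + FP, "TNR (TN+FP)")
    ppv <- safe_div(TP, TP + FP, "PPV (TP+FP)")
    f <- if (is.na(ppv) || is.na(tpr)) NA_real_
         else if (ppv + tpr <= 0) NA_real_
         else 2 * ppv * tpr / (ppv + tpr)
    auc <- if (is.na(tpr) || is.na(tnr)) NA_real_ else (tpr + tnr) / 2
    structure(list(accuracy = acc, TPR = tpr, TNR = tnr, PPV = ppv,
                   f_score = f, AUC = auc),
              class = "metrics_report")
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (nm in names(x))
    cat(sprintf("  %-8s %s\n", nm,
                if (is.na(x[[nm]])) "NA" else sprintf("%.4f", x[[nm]])))
  invisible(x)
}

#' Dice similarity coefficient between two masks
#'
#' `DSC = 2 |A & B| / (|A| + |B|)`; defined as 1 when both masks are empty
#' (agreement on absence).
#'
#' @param seg,gt [binary_mask()] objects or logical matrices of equal
#'   dimensions.
#' @return A single value in `[0, 1]`.
#' @export
dice <- function(seg, gt) {
  a <- mask_matrix(seg); b <- mask_matrix(gt)
  if (!identical(dim(a), dim(b)))
    stop("mask dimensions differ", call. = FALSE)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Pixel-level confusion counts of a segmentation against ground truth
#'
#' Full-frame counting: `TP = |seg & gt|`, `FP = |seg & !gt|`,
#' `FN = |!seg & gt|`, `TN` the remainder, summing to the pixel count.
#'
#' @inheritParams dice
#' @return A [confusion_counts()].
#' @export
pixel_confusion <- function(seg, gt) {
  a <- mask_matrix(seg); b <- mask_matrix(gt)
  if (!identical(dim(a), dim(b)))
    stop("mask dimensions differ", call. = FALSE)
  tp <- sum(a & b); fp <- sum(a & !b); fn <- sum(!a & b)
  confusion_counts(TP = tp, TN = length(a) - tp - fp - fn, FP = fp, FN = fn)
}

#' Per-image segmentation evaluation table
#'
#' One row per image in the column order DSC, PPV, TPR, TNR, F-Score, AUC,
#' Accuracy (values as percentages), plus a final `Average` row.
#'
#' @param segs list of segmentation masks.
#' @param gts list of ground-truth masks, same length.
#' @param names optional row names.
#' @return A data frame.
#' @export
segmentation_report <- function(segs, gts, names = NULL) {
  stopifnot(length(segs) == length(gts))
  rows <- lapply(seq_along(segs), function(i) {
    m <- confusion_metrics(pixel_confusion(segs[[i]], gts[[i]]))
    data.frame(image = if (is.null(names)) as.character(i) else names[i],
               DSC = 100 * dice(segs[[i]], gts[[i]]),
               PPV = 100 * m$PPV, TPR = 100 * m$TPR, TNR = 100 * m$TNR,
               F_Score = 100 * m$f_score, AUC = 100 * m$AUC,
               Accuracy = 100 * m$accuracy)
  })
  df <- do.call(rbind, rows)
  avg <- data.frame(image = "Average", t(colMeans(df[, -1], na.rm = TRUE)))
  names(avg) <- names(df)
  rbind(df, avg)
}
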
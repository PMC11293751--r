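#' Labeled slice dataset
#'
#' A `mri_dataset` holds references to (or in-memory copies of) grayscale
#' slices with a two-class label, `"normal"` or `"abnormal"`, and optional
#' ground-truth masks.
#'
#' @param labels character vector of labels in `{"normal", "abnormal"}`.
#' @param images optional list of [gray_image()] objects (in-memory dataset).
#' @param paths optional character vector of image file paths.
#' @param masks optional list of [binary_mask()] or `NA`, or mask paths.
#' @return An object of class `mri_dataset`.
#' @export
mri_dataset <- function(labels, images = NULL, paths = NULL, masks = NULL) {
  labels <- as.character(labels)
  bad <- which(!labels %in% c("normal", "abnormal"))
  if (length(bad) > 0L)
    stop(sprintf("unknown label '%s' in row %d (allowed: normal, abnormal)",
                 labels[bad[1]], bad[1]), call. = FALSE)
  n <- length(labels)
  if (!is.null(images) && length(images) != n)
    stop("'images' length must match 'labels'", call. = FALSE)
  if (!is.null(paths) && length(paths) != n)
    stop("'paths' length must match 'labels'", call. = FALSE)
  if (!is.null(masks) && length(masks) != n)
    stop("'masks' length must match 'labels'", call. = FALSE)
  structure(list(labels = labels, images = images, paths = paths,
                 masks = masks),
            class = "mri_dataset")
}

#' @export
length.mri_dataset <- function(x) length(x$labels)

#' @export
print.mri_dataset <- function(x, ...) {
  cc <- dataset_counts(x)
  cat(sprintf("<mri_dataset: %d items (%d abnormal, %d normal), %s>\n",
              length(x), cc[["abnormal"]], cc[["normal"]],
              if (is.null(x$images)) "on disk" else "in memory"))
  invisible(x)
}

#' Per-class item counts of a dataset
#'
#' @param ds an [mri_dataset()].
#' @return Named integer vector with elements `abnormal` and `normal`.
#' @export
dataset_counts <- function(ds) {
  c(abnormal = sum(ds$labels == "abnormal"),
    normal = sum(ds$labels == "normal"))
}

#' Fetch the i-th image of a dataset
#'
#' Resolves in-memory storage or reads from the recorded path.
#'
#' @param ds an [mri_dataset()].
#' @param i item index.
#' @return A [gray_image()].
#' @export
dataset_image <- function(ds, i) {
  if (!is.null(ds$images)) return(as_gray_image(ds$images[[i]]))
  read_image(ds$paths[i])
}

#' Fetch the i-th ground-truth mask of a dataset, or NULL
#'
#' @param ds an [mri_dataset()].
#' @param i item index.
#' @return A [binary_mask()] or `NULL` when no mask is recorded.
#' @export
dataset_mask <- function(ds, i) {
  if (is.null(ds$masks)) return(NULL)
  m <- ds$masks[[i]]
  if (is.null(m) || (length(m) == 1L && is.na(m))) return(NULL)
  if (is.character(m)) return(read_mask(m))
  if (inherits(m, "binary_mask")) return(m)
  binary_mask(m, role = "truth")
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with header `path,label` and an optional third
#' column `mask`; labels must be `normal` or `abnormal`. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return An [mri_dataset()] referencing files on disk.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest '%s' not found", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(df)))
    stop("manifest must have columns 'path' and 'label'", call. = FALSE)
  if (nrow(df) == 0L)
    return(mri_dataset(character(0), paths = character(0)))
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | p == "", NA_character_,
           ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p)))
  }
  masks <- NULL
  if ("mask" %in% names(df)) masks <- as.list(resolve(df$mask))
  mri_dataset(df$label, paths = resolve(df$path), masks = masks)
}

#' Write a dataset manifest
#'
#' @param ds an [mri_dataset()] with paths.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(ds, path) {
  if (is.null(ds$paths))
    stop("dataset has no file paths; write images first", call. = FALSE)
  df <- data.frame(path = ds$paths, label = ds$labels,
                   stringsAsFactors = FALSE)
  if (!is.null(ds$masks))
    df$mask <- vapply(ds$masks, function(m)
      if (is.character(m)) m else NA_character_, character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report a data frame (e.g. per-image metric rows).
#' @param path output path without extension, or with `.csv`/`.json` (the
#'   twin file is written alongside).
#' @return Invisibly, the two paths written.
#' @export
write_report <- function(report, path) {
  stem <- sub("\\.(csv|json)$", "", path)
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  utils::write.csv(report, csv, row.names = FALSE)
  jsonlite::write_json(report, js, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(c(csv = csv, json = js))
}
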
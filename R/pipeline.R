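#' Segment one slice end to end
#'
#' Contrast enhancement (optional, on by default since thresholding reads
#' the enhanced image), multi-level Tsallis thresholding by differential
#' evolution, aggregation of the three largest thresholds, binarization and
#' morphological opening.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param params a [tsallis_params()] (default 6 thresholds, gamma 0.5).
#' @param de_cfg a [de_config()].
#' @param radius opening disk radius (default 10).
#' @param enhance apply [enhance_contrast()] first (default `TRUE`).
#' @param morph passed to [refine_mask()].
#' @return A list with `enhanced` image, `thresholds`
#'   ([threshold_vector()] with `aggregate` filled in), `raw` and `refined`
#'   [binary_mask()]s.
#' @export
segment_image <- function(img, params = tsallis_params(),
                          de_cfg = de_config(D = params$m),
                          radius = 10, enhance = TRUE,
                          morph = "opening") {
  g <- as_gray_image(img)
  enh <- if (enhance) suppressWarnings(enhance_contrast(g)) else g
  tv <- optimize_thresholds(compute_histogram(enh), params, de_cfg)
  tv$aggregate <- aggregate_threshold(tv)
  raw <- binarize(enh, tv$aggregate)
  refined <- refine_mask(raw, disk_element(radius), morph = morph)
  list(enhanced = enh, thresholds = tv, raw = raw, refined = refined)
}

#' Pipeline configuration
#'
#' Nested per-stage configuration with a global seed; unknown section names
#' are rejected.
#'
#' @param input manifest path or an [mri_dataset()].
#' @param out_dir run directory for artifacts and the report.
#' @param seed global seed (propagated to stages that do not set their own).
#' @param preprocess list: `low_tail`, `high_tail`.
#' @param classifier `NULL` to disable classification (all slices treated as
#'   abnormal), or a list with `spec` ([network_spec()]), `cfg`
#'   ([train_config()]) and optionally a pre-trained `model`.
#' @param thresholding list: `m`, `gamma`, plus [de_config()] overrides.
#' @param postprocess list: `radius`, `morph`.
#' @param evaluate logical: compute pixel metrics where masks exist.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir = tempfile("mriseg_run_"),
                            seed = 17L,
                            preprocess = list(low_tail = 0.01,
                                              high_tail = 0.99),
                            classifier = NULL,
                            thresholding = list(m = 6L, gamma = 0.5),
                            postprocess = list(radius = 10,
                                               morph = "opening"),
                            evaluate = TRUE) {
  structure(list(input = input, out_dir = out_dir, seed = as.integer(seed),
                 preprocess = preprocess, classifier = classifier,
                 thresholding = thresholding, postprocess = postprocess,
                 evaluate = evaluate),
            class = "pipeline_config")
}

#' Run the two-phase pipeline
#'
#' Enhance every slice; classify (or bypass classification when no
#' classifier is configured); segment only the slices predicted abnormal;
#' refine; evaluate against ground-truth masks where available. Artifacts,
#' the resolved configuration and a JSON run report are written into the
#' run directory, making every reported number regenerable from that
#' directory alone.
#'
#' @param cfg a [pipeline_config()].
#' @return The run report, invisibly (also written as
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ds <- if (inherits(cfg$input, "mri_dataset")) cfg$input
        else read_manifest(cfg$input)
  n <- length(ds)
  if (n == 0L) stop("pipeline input dataset is empty", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(cfg$out_dir, "run.log")
  mriseg_log("run start: %d slices, seed %d", n, cfg$seed, file = log_file)

  limits <- stretch_limits(cfg$preprocess$low_tail, cfg$preprocess$high_tail)
  stage <- function(name, i, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed on item %d: %s", name, i,
                   conditionMessage(e)), call. = FALSE))
  }

  enhanced <- vector("list", n)
  for (i in seq_len(n))
    enhanced[[i]] <- stage("enhance", i, suppressWarnings(
      enhance_contrast(dataset_image(ds, i), limits)))

  if (!is.null(cfg$classifier)) {
    model <- cfg$classifier$model
    if (is.null(model)) {
      spec <- cfg$classifier$spec %||% reduced_network_spec()
      tcfg <- cfg$classifier$cfg %||% train_config(seed = cfg$seed)
      model <- build_network(spec, seed = cfg$seed)
      fit <- stage("train", 0L,
                   train(model, mri_dataset(ds$labels, images = enhanced),
                         tcfg))
      model <- fit$model
    }
    pred <- stage("classify", 0L, predict_labels(model, enhanced))
    predicted <- pred$labels
  } else {
    predicted <- rep("abnormal", n)
  }

  m <- cfg$thresholding$m %||% 6L
  gamma <- cfg$thresholding$gamma %||% 0.5
  params <- tsallis_params(gamma = gamma, m = m)
  seg_idx <- which(predicted == "abnormal")
  rows <- list()
  for (i in seg_idx) {
    res <- stage("segment", i, segment_image(
      enhanced[[i]], params,
      de_config(D = params$m, seed = cfg$seed + i),
      radius = cfg$postprocess$radius %||% 10,
      morph = cfg$postprocess$morph %||% "opening",
      enhance = FALSE))
    write_image(res$raw, file.path(cfg$out_dir,
                                   sprintf("seg_%04d.pgm", i)))
    write_image(res$refined, file.path(cfg$out_dir,
                                       sprintf("seg_%04d_refined.pgm", i)))
    sidecar <- list(item = i, thresholds = res$thresholds$values,
                    objective = res$thresholds$objective,
                    aggregate = res$thresholds$aggregate)
    truth <- dataset_mask(ds, i)
    if (isTRUE(cfg$evaluate) && !is.null(truth))
      sidecar$dice <- dice(res$refined, truth)
    jsonlite::write_json(sidecar,
                         file.path(cfg$out_dir,
                                   sprintf("seg_%04d.json", i)),
                         auto_unbox = TRUE, digits = NA)
    rows[[length(rows) + 1L]] <- sidecar
  }

  report <- list(
    n_items = n,
    n_classified = n,
    predicted_abnormal = sum(predicted == "abnormal"),
    n_segmented = length(seg_idx),
    labels_true = ds$labels,
    labels_predicted = predicted,
    segmentation = rows,
    config = list(seed = cfg$seed,
                  preprocess = cfg$preprocess,
                  thresholding = list(m = m, gamma = gamma),
                  postprocess = cfg$postprocess,
                  classifier_enabled = !is.null(cfg$classifier)))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mriseg_log("run done: %d segmented of %d", length(seg_idx), n,
             file = log_file)
  invisible(report)
}
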
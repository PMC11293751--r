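#' Resize a grayscale image by bilinear interpolation
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param size target `c(height, width)`.
#' @return A [gray_image()] of the requested size.
#' @export
resize_image <- function(img, size) {
  p <- pixel_matrix(img)
  h1 <- nrow(p); w1 <- ncol(p)
  h2 <- as.integer(size[1]); w2 <- as.integer(size[2])
  if (h1 == h2 && w1 == w2) return(as_gray_image(img))
  sy <- (seq_len(h2) - 0.5) * h1 / h2 + 0.5
  sx <- (seq_len(w2) - 0.5) * w1 / w2 + 0.5
  y0 <- pmin(pmax(floor(sy), 1L), h1); y1 <- pmin(y0 + 1L, h1)
  x0 <- pmin(pmax(floor(sx), 1L), w1); x1 <- pmin(x0 + 1L, w1)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  a <- p[y0, x0, drop = FALSE] * (1 - fy) + p[y1, x0, drop = FALSE] * fy
  b <- p[y0, x1, drop = FALSE] * (1 - fy) + p[y1, x1, drop = FALSE] * fy
  out <- sweep(a, 2L, 1 - fx, `*`) + sweep(b, 2L, fx, `*`)
  out[out < 0] <- 0; out[out > 1] <- 1
  gray_image(out)
}

# stack a list of gray images into a (H, W, 1, N) batch, resizing on the fly
as_batch <- function(images, shape) {
  n <- length(images)
  x <- array(0, dim = c(shape[1], shape[2], 1L, n))
  for (i in seq_len(n))
    x[, , 1L, i] <- pixel_matrix(resize_image(images[[i]], shape))
  x
}

label_onehot <- function(labels) {
  # column 1 = normal, column 2 = abnormal
  y <- matrix(0, length(labels), 2L)
  y[cbind(seq_along(labels), ifelse(labels == "abnormal", 2L, 1L))] <- 1
  y
}

#' Train a classifier
#'
#' Mini-batch training with two-class cross-entropy on softmax outputs.
#' Epoch-level shuffling is seeded; with `epochs = 0` the model is returned
#' unchanged with an empty history.
#'
#' @param model an `mriseg_model` from [build_network()].
#' @param ds an [mri_dataset()] containing both classes (images are resized
#'   to the model's input shape as needed).
#' @param cfg a [train_config()].
#' @return A list with elements `model` (trained) and `history` (data frame
#'   with one row per epoch: `epoch`, `loss`, `accuracy`).
#' @export
train <- function(model, ds, cfg = train_config()) {
  if (length(unique(ds$labels)) < 2L && cfg$epochs > 0L)
    stop("training requires both classes present", call. = FALSE)
  if (cfg$epochs == 0L)
    return(list(model = model,
                history = data.frame(epoch = integer(0), loss = numeric(0),
                                     accuracy = numeric(0))))
  shape <- model$spec$input_shape
  images <- lapply(seq_len(length(ds)), function(i) dataset_image(ds, i))
  y <- label_onehot(ds$labels)
  n <- length(images)
  opt_env <- new.env()
  opt_env$state <- list()
  t_step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- c(); hits <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        take <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- as_batch(images[take], shape)
        yb <- y[take, , drop = FALSE]
        fw <- model_forward(model, xb, training = TRUE)
        model <- commit_bn_states(model, fw$states)
        sx <- softmax_xent(fw$logits, yb)
        losses <- c(losses, sx$loss)
        hits <- hits + sum(max.col(sx$probs) == max.col(yb))
        grads <- model_backward(model, fw$caches, sx$dlogits)
        t_step <- t_step + 1L
        model$params <- apply_gradients(model$params, grads, cfg, t_step,
                                        opt_env)
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = mean(losses),
                                  accuracy = hits / n))
    }
  })
  list(model = model, history = history)
}

#' Predict labels and class probabilities
#'
#' Inference-mode forward pass (batch-norm running statistics); the label is
#' the argmax of the softmax 2-vector (columns ordered normal, abnormal).
#'
#' @param model an `mriseg_model`.
#' @param images a list of [gray_image()] objects, a single image, or an
#'   [mri_dataset()].
#' @param batch_size inference batch size.
#' @return A list with `labels` (character) and `probs` (N x 2 matrix with
#'   columns `normal`, `abnormal`).
#' @export
predict_labels <- function(model, images, batch_size = 32L) {
  if (inherits(images, "mri_dataset"))
    images <- lapply(seq_len(length(images)),
                     function(i) dataset_image(images, i))
  if (is_gray_image(images) || is.matrix(images)) images <- list(images)
  shape <- model$spec$input_shape
  n <- length(images)
  probs <- matrix(0, n, 2L, dimnames = list(NULL, c("normal", "abnormal")))
  for (start in seq(1L, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    xb <- as_batch(images[take], shape)
    fw <- model_forward(model, xb, training = FALSE)
    probs[take, ] <- softmax_probs(fw$logits)
  }
  list(labels = c("normal", "abnormal")[max.col(probs, ties.method = "last")],
       probs = probs)
}

# stratified fold assignment preserving class ratio within +/- 1 item
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop(sprintf("class '%s' has fewer items (%d) than folds (%d)",
                     cl, length(idx), k), call. = FALSE)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified K-fold cross-validation
#'
#' Splits the dataset into stratified folds, trains a fresh He-initialized
#' model per fold (optionally augmenting the training folds only, after the
#' split), evaluates on the held-out fold with `abnormal` as the positive
#' class, and summarizes each metric as mean and sample standard deviation
#' across folds.
#'
#' @param ds an [mri_dataset()] with at least `folds` items per class.
#' @param cfg a [train_config()] (`folds` >= 2).
#' @param spec a [network_spec()]; default the reduced instance.
#' @param augment_cfg optional [augment_config()] applied to training folds
#'   only.
#' @return A list with `folds` (per-fold list of `fold`, `counts`,
#'   `metrics`), `summary` (data frame of mean/sd per metric) and
#'   `assignments` (fold index per item).
#' @export
crossvalidate <- function(ds, cfg = train_config(), spec = NULL,
                          augment_cfg = NULL) {
  if (cfg$folds < 2L) stop("'folds' must be >= 2", call. = FALSE)
  if (is.null(spec)) spec <- reduced_network_spec()
  fold <- stratified_folds(ds$labels, cfg$folds, cfg$seed)
  results <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    tr_idx <- which(fold != f); va_idx <- which(fold == f)
    tr <- subset_dataset(ds, tr_idx)
    if (!is.null(augment_cfg)) tr <- augment_dataset(tr, augment_cfg)
    model <- build_network(spec, seed = cfg$seed + f)
    fit <- train(model, tr, cfg)
    pred <- predict_labels(fit$model,
                           lapply(va_idx, function(i) dataset_image(ds, i)))
    truth <- ds$labels[va_idx]
    counts <- confusion_counts(
      TP = sum(pred$labels == "abnormal" & truth == "abnormal"),
      TN = sum(pred$labels == "normal" & truth == "normal"),
      FP = sum(pred$labels == "abnormal" & truth == "normal"),
      FN = sum(pred$labels == "normal" & truth == "abnormal"))
    results[[f]] <- list(fold = f, counts = counts,
                         metrics = suppressWarnings(confusion_metrics(counts)),
                         history = fit$history)
  }
  metric_names <- c("accuracy", "TPR", "TNR", "PPV", "f_score", "AUC")
  summ <- do.call(rbind, lapply(metric_names, function(mn) {
    vals <- vapply(results, function(r) r$metrics[[mn]], numeric(1))
    data.frame(metric = mn, mean = mean(vals, na.rm = TRUE),
               sd = stats::sd(vals, na.rm = TRUE))
  }))
  list(folds = results, summary = summ, assignments = fold)
}

#' Subset a dataset by item indices
#'
#' @param ds an [mri_dataset()].
#' @param idx integer indices.
#' @return An [mri_dataset()].
#' @export
subset_dataset <- function(ds, idx) {
  mri_dataset(ds$labels[idx],
              images = if (!is.null(ds$images)) ds$images[idx] else NULL,
              paths = if (!is.null(ds$paths)) ds$paths[idx] else NULL,
              masks = if (!is.null(ds$masks)) ds$masks[idx] else NULL)
}
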
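test_that("parameter counting matches hand counts on toy models", {
  empty <- structure(list(spec = NULL, params = list()),
                     class = "mriseg_model")
  expect_identical(count_parameters(empty)$total, 0L)

  # 1x1 conv (1 -> 32, no bias) + batch norm: 32 weights + 64 trainable BN
  toy <- structure(list(spec = NULL, params = list(
    list(conv = list(W = matrix(0, 1, 32), b = NULL, k = 1L),
         bn = mriseg:::new_bn(32L)))), class = "mriseg_model")
  pc <- count_parameters(toy)
  expect_identical(pc$trainable, 96L)
  expect_identical(pc$non_trainable, 64L)

  # with bias the trainable count grows by exactly the 32 bias terms
  toy$params[[1]]$conv$b <- numeric(32)
  expect_identical(count_parameters(toy)$trainable, 128L)
})

test_that("resolved network reproduces the reference parameter totals", {
  model <- build_network(resolved_network_spec(), seed = 1)
  pc <- count_parameters(model)
  expect_identical(pc$trainable, 549890L)
  expect_identical(pc$non_trainable, 3904L)
  expect_identical(pc$total, 553794L)
  # counts are invariant to the initialization seed
  pc2 <- count_parameters(build_network(resolved_network_spec(), seed = 99))
  expect_identical(pc, pc2)
})

test_that("He-initialized conv layers have variance close to 2/fan_in", {
  model <- build_network(resolved_network_spec(), seed = 5)
  checked <- 0L
  for (p in model$params) {
    for (nm in c("conv", "c2", "b2b")) {
      layer <- p[[nm]]
      if (is.null(layer) || !is.list(layer) || is.null(layer$W)) next
      if (length(layer$W) < 1000) next
      fan_in <- nrow(layer$W)
      v <- stats::var(as.vector(layer$W))
      expect_lt(abs(v - 2 / fan_in) / (2 / fan_in), 0.2)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 3L)
})

test_that("forward pass emits a normalized 2-class distribution", {
  spec <- reduced_network_spec(input_shape = c(32L, 32L), width_scale = 0.125)
  model <- build_network(spec, seed = 3)
  set.seed(4)
  x <- array(runif(32 * 32 * 3), dim = c(32, 32, 1, 3))
  fw <- mriseg:::model_forward(model, x, training = FALSE)
  probs <- mriseg:::softmax_probs(fw$logits)
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("predict returns one label per image and is deterministic", {
  spec <- reduced_network_spec(input_shape = c(32L, 32L), width_scale = 0.125)
  model <- build_network(spec, seed = 6)
  set.seed(7)
  imgs <- replicate(4, gray_image(matrix(runif(1024), 32, 32)),
                    simplify = FALSE)
  pred <- predict_labels(model, imgs)
  expect_length(pred$labels, 4L)
  expect_true(all(pred$labels %in% c("normal", "abnormal")))
  dup <- predict_labels(model, list(imgs[[1]], imgs[[1]]))
  expect_identical(dup$probs[1, ], dup$probs[2, ])
})

test_that("train honors the no-op, validation and determinism contracts", {
  spec <- reduced_network_spec(input_shape = c(16L, 16L), width_scale = 0.0625)
  model <- build_network(spec, seed = 8)
  ds <- blob_dataset(3, 3, size = 16L, seed = 9)

  noop <- train(model, ds, train_config(epochs = 0L))
  expect_identical(noop$model$params, model$params)
  expect_identical(nrow(noop$history), 0L)

  onecls <- mri_dataset(rep("abnormal", 3), images = ds$images[1:3])
  expect_error(train(model, onecls, train_config(epochs = 1L)),
               "both classes")

  cfg <- train_config(optimizer = "adam", batch_size = 3L, epochs = 1L,
                      seed = 42)
  a <- train(model, ds, cfg)
  b <- train(model, ds, cfg)
  expect_identical(a$history$loss[1], b$history$loss[1])
})

test_that("three Adam epochs separate an easy two-blob image set", {
  spec <- reduced_network_spec(input_shape = c(32L, 32L), width_scale = 0.25)
  model <- build_network(spec, seed = 10)
  ds <- blob_dataset(16, 16, size = 32L, seed = 11)
  fit <- train(model, ds, train_config(optimizer = "adam", batch_size = 4L,
                                       epochs = 3L, seed = 12))
  expect_identical(nrow(fit$history), 3L)
  expect_lt(fit$history$loss[3], fit$history$loss[1])
  pred <- predict_labels(fit$model, ds)
  expect_gte(mean(pred$labels == ds$labels), 0.95)
})

test_that("every optimizer family takes a finite training step", {
  spec <- reduced_network_spec(input_shape = c(16L, 16L), width_scale = 0.0625)
  ds <- blob_dataset(2, 2, size = 16L, seed = 13)
  for (opt in c("sgdm", "adamax", "adagrad", "adadelta", "rmsprop",
                "nadam")) {
    model <- build_network(spec, seed = 14)
    fit <- train(model, ds,
                 train_config(optimizer = opt, batch_size = 4L,
                              epochs = 1L, seed = 15))
    expect_true(is.finite(fit$history$loss[1]), info = opt)
    expect_false(identical(fit$model$params, model$params), info = opt)
  }
})

test_that("stratified folds partition items and preserve class ratio", {
  labels <- c(rep("abnormal", 25), rep("normal", 10))
  fold <- mriseg:::stratified_folds(labels, 5L, seed = 16)
  expect_identical(sort(unique(fold)), 1:5)
  for (f in 1:5) {
    expect_identical(sum(fold == f), 7L)
    expect_identical(sum(fold == f & labels == "abnormal"), 5L)
  }
  expect_error(mriseg:::stratified_folds(c("normal", "abnormal"), 5L, 1),
               "fewer items")
})

test_that("cross-validation summarizes fold metrics with mean and sample SD", {
  spec <- reduced_network_spec(input_shape = c(16L, 16L), width_scale = 0.0625)
  ds <- blob_dataset(8, 8, size = 16L, seed = 17)
  cv <- crossvalidate(ds, train_config(optimizer = "adam", batch_size = 4L,
                                       epochs = 2L, folds = 2L, seed = 18),
                      spec = spec)
  expect_length(cv$folds, 2L)
  expect_true(all(table(cv$assignments) == 8L))
  accs <- vapply(cv$folds, function(f) f$metrics$accuracy, numeric(1))
  srow <- cv$summary[cv$summary$metric == "accuracy", ]
  expect_equal(srow$mean, mean(accs))
  expect_equal(srow$sd, stats::sd(accs))
  counts <- vapply(cv$folds, function(f)
    f$counts$TP + f$counts$TN + f$counts$FP + f$counts$FN, numeric(1))
  expect_identical(as.integer(counts), c(8L, 8L))
})
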
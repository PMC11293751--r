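#' Training configuration
#'
#' Optimizer hyperparameter defaults follow the reference settings:
#' learning rate `alpha = 0.001` for every optimizer; `beta1 = 0.9`,
#' `beta2 = 0.999`, `epsilon = 1e-7` for the adaptive-moment family;
#' `rho = 0.95` (adadelta) or `0.9` (rmsprop); momentum `0.9` for SGDM;
#' batch size 64; 30 epochs; 5 folds.
#'
#' @param optimizer one of `"sgdm"`, `"adam"`, `"adamax"`, `"adagrad"`,
#'   `"adadelta"`, `"rmsprop"`, `"nadam"`.
#' @param alpha learning rate.
#' @param beta1,beta2 first/second moment decay rates.
#' @param epsilon numerical-stability constant.
#' @param rho decay factor for adadelta/rmsprop (default per optimizer).
#' @param momentum SGDM momentum.
#' @param batch_size,epochs,folds,seed training-loop controls.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgdm", "adamax", "adagrad",
                                       "adadelta", "rmsprop", "nadam"),
                         alpha = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, rho = NULL, momentum = 0.9,
                         batch_size = 64L, epochs = 30L, folds = 5L,
                         seed = 17L) {
  optimizer <- match.arg(tolower(optimizer[1]),
                         c("adam", "sgdm", "adamax", "adagrad", "adadelta",
                           "rmsprop", "nadam"))
  if (is.null(rho))
    rho <- switch(optimizer, adadelta = 0.95, rmsprop = 0.9, 0.9)
  structure(list(optimizer = optimizer, alpha = alpha, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon, rho = rho,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "train_config")
}

# one optimizer step on a single tensor; st is this tensor's state list
optim_step <- function(w, g, st, cfg, t) {
  a <- cfg$alpha; e <- cfg$epsilon
  switch(cfg$optimizer,
    sgdm = {
      if (is.null(st$v)) st$v <- 0 * w
      st$v <- cfg$momentum * st$v - a * g
      w <- w + st$v
      list(w = w, st = st)
    },
    adam = {
      if (is.null(st$m)) { st$m <- 0 * w; st$v <- 0 * w }
      st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
      st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g^2
      mh <- st$m / (1 - cfg$beta1^t)
      vh <- st$v / (1 - cfg$beta2^t)
      list(w = w - a * mh / (sqrt(vh) + e), st = st)
    },
    adamax = {
      if (is.null(st$m)) { st$m <- 0 * w; st$u <- 0 * w }
      st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
      st$u <- pmax(cfg$beta2 * st$u, abs(g))
      list(w = w - (a / (1 - cfg$beta1^t)) * st$m / (st$u + e), st = st)
    },
    adagrad = {
      if (is.null(st$G)) st$G <- 0 * w
      st$G <- st$G + g^2
      list(w = w - a * g / (sqrt(st$G) + e), st = st)
    },
    adadelta = {
      if (is.null(st$G)) { st$G <- 0 * w; st$D <- 0 * w }
      st$G <- cfg$rho * st$G + (1 - cfg$rho) * g^2
      upd <- sqrt(st$D + e) / sqrt(st$G + e) * g
      st$D <- cfg$rho * st$D + (1 - cfg$rho) * upd^2
      list(w = w - a * upd, st = st)
    },
    rmsprop = {
      if (is.null(st$G)) st$G <- 0 * w
      st$G <- cfg$rho * st$G + (1 - cfg$rho) * g^2
      list(w = w - a * g / (sqrt(st$G) + e), st = st)
    },
    nadam = {
      if (is.null(st$m)) { st$m <- 0 * w; st$v <- 0 * w }
      st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
      st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g^2
      mh <- st$m / (1 - cfg$beta1^(t + 1))
      vh <- st$v / (1 - cfg$beta2^t)
      step <- cfg$beta1 * mh + (1 - cfg$beta1) * g / (1 - cfg$beta1^t)
      list(w = w - a * step / (sqrt(vh) + e), st = st)
    },
    stop("unknown optimizer"))
}

# apply one update to every trainable tensor in the nested params/grads
# trees; opt_env carries per-tensor state keyed by path
apply_gradients <- function(params, grads, cfg, t, opt_env) {
  step_tree <- function(p, g, path) {
    for (nm in names(g)) {
      if (is.null(g[[nm]])) next
      key <- paste(path, nm, sep = "/")
      if (is.list(g[[nm]])) {
        p[[nm]] <- step_tree(p[[nm]], g[[nm]], key)
      } else {
        st <- opt_env$state[[key]]
        if (is.null(st)) st <- list()
        res <- optim_step(p[[nm]], g[[nm]], st, cfg, t)
        p[[nm]] <- res$w
        opt_env$state[[key]] <- res$st
      }
    }
    p
  }
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]])) next
    params[[i]] <- step_tree(params[[i]], grads[[i]], as.character(i))
  }
  params
}
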
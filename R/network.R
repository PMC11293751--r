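# Block-structured CNN: stem, projection ("convolution") blocks, residual
# identity blocks, inception blocks, and an avgpool/1x1-conv/dense head.

he_conv <- function(k, cin, cout, bias = TRUE) {
  W <- matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
              k * k * cin, cout)
  list(W = W, b = if (bias) numeric(cout) else NULL, k = k)
}

new_bn <- function(ch) {
  list(gamma = rep(1, ch), beta = numeric(ch),
       mean = numeric(ch), var = rep(1, ch))
}

#' Network specification
#'
#' Assembles the block list of the classifier. The default (resolved)
#' configuration is loaded by [resolved_network_spec()]; a filter-scaled
#' instance for quick experiments comes from [reduced_network_spec()].
#'
#' @param input_shape integer `c(U, V)` of the grayscale input.
#' @param blocks list of block descriptors (`kind` plus filters/stride).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_shape, blocks) {
  stopifnot(length(input_shape) >= 2L)
  structure(list(input_shape = as.integer(input_shape[1:2]), blocks = blocks),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec %dx%dx1, %d blocks>\n",
              x$input_shape[1], x$input_shape[2], length(x$blocks)))
  for (b in x$blocks)
    cat(" -", b$kind,
        if (!is.null(b$filters)) paste0("(", paste(b$filters, collapse = ","),
                                        ")") else "",
        if (!is.null(b$stride) && b$stride != 1L) paste0("s", b$stride) else "",
        "\n")
  invisible(x)
}

#' The resolved full-scale network specification
#'
#' The block ordering and filter assignment whose parameter count equals the
#' reference totals (553,794 parameters: 549,890 trainable, 3,904
#' non-trainable batch-norm statistics, for 256 x 256 x 1 input). The
#' configuration is frozen in `inst/extdata/network_config.json` and read
#' from there.
#'
#' @param input_shape input height/width (default `c(256, 256)`).
#' @return A [network_spec()].
#' @export
resolved_network_spec <- function(input_shape = c(256L, 256L)) {
  cfg_path <- system.file("extdata", "network_config.json",
                          package = "mriseg", mustWork = TRUE)
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  blocks <- lapply(seq_along(cfg$blocks$kind), function(i) {
    list(kind = cfg$blocks$kind[i],
         filters = as.integer(cfg$filters[[i]]),
         stride = as.integer(cfg$blocks$stride[i]))
  })
  network_spec(input_shape, blocks)
}

#' A filter-scaled ("reduced") instance of the same topology
#'
#' Same block sequence as [resolved_network_spec()] with every filter count
#' multiplied by `width_scale` (floored, minimum 2). Suitable for desk-scale
#' training runs.
#'
#' @param input_shape input height/width (default `c(64, 64)`).
#' @param width_scale multiplier applied to all filter counts.
#' @return A [network_spec()].
#' @export
reduced_network_spec <- function(input_shape = c(64L, 64L),
                                 width_scale = 0.25) {
  spec <- resolved_network_spec(input_shape)
  spec$blocks <- lapply(spec$blocks, function(b) {
    if (!is.null(b$filters))
      b$filters <- pmax(2L, as.integer(floor(b$filters * width_scale)))
    b
  })
  spec
}

# ---- block constructors -------------------------------------------------

init_block <- function(b, cin) {
  kind <- b$kind
  if (kind == "stem") {
    f <- b$filters[1]
    list(conv = he_conv(7L, cin, f), bn = new_bn(f), cout = f)
  } else if (kind == "conv_block") {
    f <- b$filters  # f1, f2, f3
    list(c1 = he_conv(1L, cin, f[1]), bn1 = new_bn(f[1]),
         c2 = he_conv(1L, f[1], f[2]), bn2 = new_bn(f[2]),
         c3 = he_conv(1L, f[2], f[3]), bn3 = new_bn(f[3]),
         c4 = he_conv(1L, f[3], f[3]), bn4 = new_bn(f[3]),
         sc = he_conv(1L, cin, f[3]),
         cout = f[3])
  } else if (kind == "identity_block") {
    f <- b$filters
    if (cin != f[3])
      stop(sprintf(
        "identity block needs input channels == F3 (%d != %d)", cin, f[3]),
        call. = FALSE)
    list(c1 = he_conv(1L, cin, f[1]), bn1 = new_bn(f[1]),
         c2 = he_conv(3L, f[1], f[2]), bn2 = new_bn(f[2]),
         c3 = he_conv(1L, f[2], f[3]), bn3 = new_bn(f[3]),
         cout = f[3])
  } else if (kind == "inception_block") {
    f <- b$filters  # f1..f6
    list(b1 = he_conv(1L, cin, f[1]),
         b2a = he_conv(1L, cin, f[2]), b2b = he_conv(3L, f[2], f[3]),
         b3a = he_conv(1L, cin, f[4]), b3b = he_conv(5L, f[4], f[5]),
         b4 = he_conv(1L, cin, f[6]),
         cout = f[1] + f[3] + f[5] + f[6])
  } else if (kind == "head") {
    f <- b$filters[1]  # 64
    list(conv = he_conv(1L, cin, f, bias = FALSE), bn = new_bn(f),
         f = f, cout = 2L)
  } else stop("unknown block kind: ", kind, call. = FALSE)
}

# dense layer of the head depends on the spatial size reaching it; resolved
# lazily on the first forward pass / during build via shape inference
head_spatial <- function(input_shape, blocks) {
  h <- input_shape[1]; w <- input_shape[2]
  ceil_div <- function(n, s) as.integer(ceiling(n / s))
  h <- ceil_div(h, 2L); w <- ceil_div(w, 2L)  # stem conv s2
  h <- ceil_div(h, 2L); w <- ceil_div(w, 2L)  # stem maxpool s2
  for (b in blocks) {
    if (b$kind == "conv_block" && !is.null(b$stride) && b$stride > 1L) {
      h <- ceil_div(h, b$stride); w <- ceil_div(w, b$stride)
    }
  }
  # head average pool 5x5 stride 3, valid (kernel shrinks on tiny maps)
  k <- min(5L, h, w)
  c((h - k) %/% 3L + 1L, (w - k) %/% 3L + 1L)
}

#' Build (initialize) a network from a specification
#'
#' Conv weights use He initialization (variance `2 / fan_in`), biases start
#' at zero, batch-norm scale/shift at 1/0 with running statistics 0/1.
#' Every conv carries a bias except the head 1x1 projection, which is
#' followed by batch norm.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the weight draw.
#' @return An object of class `mriseg_model` holding the spec and all
#'   parameters.
#' @export
build_network <- function(spec, seed = 17L) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed(seed, {
    cin <- 1L
    params <- vector("list", length(spec$blocks))
    for (i in seq_along(spec$blocks)) {
      params[[i]] <- init_block(spec$blocks[[i]], cin)
      cin <- params[[i]]$cout
    }
    hs <- head_spatial(spec$input_shape, spec$blocks)
    ih <- which(vapply(spec$blocks, function(b) b$kind == "head",
                       logical(1)))
    if (length(ih) == 1L) {
      fdim <- hs[1] * hs[2] * params[[ih]]$f
      params[[ih]]$dense <- list(
        W = matrix(stats::rnorm(fdim * 2L, 0, sqrt(2 / fdim)), fdim, 2L),
        b = numeric(2L))
    }
    structure(list(spec = spec, params = params), class = "mriseg_model")
  })
}

#' @export
print.mriseg_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<mriseg_model %dx%dx1: %s trainable + %s non-trainable = %s>\n",
              x$spec$input_shape[1], x$spec$input_shape[2],
              format(pc$trainable, big.mark = ","),
              format(pc$non_trainable, big.mark = ","),
              format(pc$trainable + pc$non_trainable, big.mark = ",")))
  invisible(x)
}

#' Count model parameters
#'
#' Trainable: convolution and dense weights and biases, batch-norm scale and
#' shift. Non-trainable: batch-norm running mean and variance (2 per
#' channel). Counts are invariant to batch size and to the initialization
#' seed.
#'
#' @param model an `mriseg_model` from [build_network()].
#' @return A list with integer fields `trainable`, `non_trainable`, `total`.
#' @export
count_parameters <- function(model) {
  tr <- 0L; ntr <- 0L
  walk <- function(x, nm) {
    if (is.list(x)) {
      for (n in names(x)) walk(x[[n]], n)
    } else if (is.numeric(x)) {
      if (nm %in% c("mean", "var")) ntr <<- ntr + length(x)
      else if (nm %in% c("W", "b", "gamma", "beta")) tr <<- tr + length(x)
    }
  }
  for (p in model$params) walk(p, "")
  list(trainable = tr, non_trainable = ntr, total = tr + ntr)
}

# ---- forward / backward -------------------------------------------------

cbr_forward <- function(x, conv, bn, stride, training, relu = TRUE,
                        padding = "same") {
  cf <- conv_forward(x, conv$W, conv$b, conv$k, stride, padding)
  bf <- bn_forward(cf$out, bn$gamma, bn$beta,
                   list(mean = bn$mean, var = bn$var), training)
  if (relu) {
    rf <- relu_forward(bf$out)
    out <- rf$out; rmask <- rf$cache
  } else {
    out <- bf$out; rmask <- NULL
  }
  list(out = out, cache = list(conv = cf$cache, bn = bf$cache,
                               rmask = rmask),
       state = bf$state)
}

cbr_backward <- function(dout, cache) {
  if (!is.null(cache$rmask)) dout <- relu_backward(dout, cache$rmask)
  # batch-norm parameter grads
  d <- cache$bn$d
  C <- d[3]
  dym <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = C)
  dgamma <- colSums(dym * cache$bn$xhat)
  dbeta <- colSums(dym)
  dx_bn <- bn_backward(dout, cache$bn)
  cb <- conv_backward(dx_bn, cache$conv)
  list(dx = cb$dx,
       grads = list(conv = list(W = cb$dW, b = cb$db),
                    bn = list(gamma = dgamma, beta = dbeta)))
}

block_forward <- function(b, p, x, training) {
  kind <- b$kind
  if (kind == "stem") {
    s1 <- cbr_forward(x, p$conv, p$bn, 2L, training)
    mp <- maxpool_forward(s1$out, 3L, 2L)
    list(out = mp$out,
         cache = list(s1 = s1$cache, mp = mp$cache),
         state = list(bn = s1$state))
  } else if (kind == "conv_block") {
    s <- if (is.null(b$stride)) 1L else b$stride
    a1 <- cbr_forward(x, p$c1, p$bn1, s, training)
    a2 <- cbr_forward(a1$out, p$c2, p$bn2, 1L, training)
    a3 <- cbr_forward(a2$out, p$c3, p$bn3, 1L, training)
    a4 <- cbr_forward(a3$out, p$c4, p$bn4, 1L, training, relu = FALSE)
    sc <- conv_forward(x, p$sc$W, p$sc$b, 1L, s, "same")
    summ <- a4$out + sc$out
    rf <- relu_forward(summ)
    list(out = rf$out,
         cache = list(a1 = a1$cache, a2 = a2$cache, a3 = a3$cache,
                      a4 = a4$cache, sc = sc$cache, rmask = rf$cache),
         state = list(bn1 = a1$state, bn2 = a2$state, bn3 = a3$state,
                      bn4 = a4$state))
  } else if (kind == "identity_block") {
    a1 <- cbr_forward(x, p$c1, p$bn1, 1L, training)
    a2 <- cbr_forward(a1$out, p$c2, p$bn2, 1L, training)
    a3 <- cbr_forward(a2$out, p$c3, p$bn3, 1L, training, relu = FALSE)
    summ <- a3$out + x
    rf <- relu_forward(summ)
    list(out = rf$out,
         cache = list(a1 = a1$cache, a2 = a2$cache, a3 = a3$cache,
                      rmask = rf$cache),
         state = list(bn1 = a1$state, bn2 = a2$state, bn3 = a3$state))
  } else if (kind == "inception_block") {
    r <- function(cf) { rf <- relu_forward(cf$out)
      list(out = rf$out, conv = cf$cache, rmask = rf$cache) }
    b1 <- r(conv_forward(x, p$b1$W, p$b1$b, 1L, 1L, "same"))
    b2a <- r(conv_forward(x, p$b2a$W, p$b2a$b, 1L, 1L, "same"))
    b2b <- r(conv_forward(b2a$out, p$b2b$W, p$b2b$b, 3L, 1L, "same"))
    b3a <- r(conv_forward(x, p$b3a$W, p$b3a$b, 1L, 1L, "same"))
    b3b <- r(conv_forward(b3a$out, p$b3b$W, p$b3b$b, 5L, 1L, "same"))
    mp <- maxpool_forward(x, 3L, 1L)
    b4 <- r(conv_forward(mp$out, p$b4$W, p$b4$b, 1L, 1L, "same"))
    d <- dim(x)
    parts <- list(b1$out, b2b$out, b3b$out, b4$out)
    chans <- vapply(parts, function(a) dim(a)[3], integer(1))
    out <- array(0, dim = c(dim(b1$out)[1:2], sum(chans), d[4]))
    at <- 0L
    for (pt in parts) {
      cc <- dim(pt)[3]
      out[, , (at + 1L):(at + cc), ] <- pt
      at <- at + cc
    }
    list(out = out,
         cache = list(b1 = b1, b2a = b2a, b2b = b2b, b3a = b3a, b3b = b3b,
                      mp = mp$cache, b4 = b4, chans = chans),
         state = NULL)
  } else if (kind == "head") {
    kp <- min(5L, dim(x)[1], dim(x)[2])
    ap <- avgpool_forward(x, kp, 3L)
    cb <- cbr_forward(ap$out, p$conv, p$bn, 1L, training)
    dn <- dense_forward(cb$out, p$dense$W, p$dense$b)
    list(out = dn$out,
         cache = list(ap = ap$cache, cb = cb$cache, dn = dn$cache),
         state = list(bn = cb$state))
  } else stop("unknown block kind")
}

block_backward <- function(b, p, cache, dout) {
  kind <- b$kind
  if (kind == "stem") {
    d1 <- maxpool_backward(dout, cache$mp)
    bb <- cbr_backward(d1, cache$s1)
    list(dx = bb$dx, grads = list(conv = bb$grads$conv, bn = bb$grads$bn))
  } else if (kind == "conv_block") {
    dout <- relu_backward(dout, cache$rmask)
    b4 <- cbr_backward(dout, cache$a4)
    b3 <- cbr_backward(b4$dx, cache$a3)
    b2 <- cbr_backward(b3$dx, cache$a2)
    b1 <- cbr_backward(b2$dx, cache$a1)
    sc <- conv_backward(dout, cache$sc)
    list(dx = b1$dx + sc$dx,
         grads = list(c1 = b1$grads$conv, bn1 = b1$grads$bn,
                      c2 = b2$grads$conv, bn2 = b2$grads$bn,
                      c3 = b3$grads$conv, bn3 = b3$grads$bn,
                      c4 = b4$grads$conv, bn4 = b4$grads$bn,
                      sc = list(W = sc$dW, b = sc$db)))
  } else if (kind == "identity_block") {
    dout <- relu_backward(dout, cache$rmask)
    b3 <- cbr_backward(dout, cache$a3)
    b2 <- cbr_backward(b3$dx, cache$a2)
    b1 <- cbr_backward(b2$dx, cache$a1)
    list(dx = b1$dx + dout,
         grads = list(c1 = b1$grads$conv, bn1 = b1$grads$bn,
                      c2 = b2$grads$conv, bn2 = b2$grads$bn,
                      c3 = b3$grads$conv, bn3 = b3$grads$bn))
  } else if (kind == "inception_block") {
    ch <- cache$chans
    ends <- cumsum(ch)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    split_g <- lapply(seq_along(ch), function(i)
      dout[, , starts[i]:ends[i], , drop = FALSE])
    bk <- function(part, g) {
      g <- relu_backward(g, part$rmask)
      conv_backward(g, part$conv)
    }
    g1 <- bk(cache$b1, split_g[[1]])
    g2b <- bk(cache$b2b, split_g[[2]])
    g2a <- bk(cache$b2a, g2b$dx)
    g3b <- bk(cache$b3b, split_g[[3]])
    g3a <- bk(cache$b3a, g3b$dx)
    g4 <- bk(cache$b4, split_g[[4]])
    gmp <- maxpool_backward(g4$dx, cache$mp)
    list(dx = g1$dx + g2a$dx + g3a$dx + gmp,
         grads = list(b1 = list(W = g1$dW, b = g1$db),
                      b2a = list(W = g2a$dW, b = g2a$db),
                      b2b = list(W = g2b$dW, b = g2b$db),
                      b3a = list(W = g3a$dW, b = g3a$db),
                      b3b = list(W = g3b$dW, b = g3b$db),
                      b4 = list(W = g4$dW, b = g4$db)))
  } else if (kind == "head") {
    dn <- dense_backward(dout, cache$dn)
    cb <- cbr_backward(dn$dx, cache$cb)
    dap <- avgpool_backward(cb$dx, cache$ap)
    list(dx = dap,
         grads = list(conv = cb$grads$conv, bn = cb$grads$bn,
                      dense = list(W = dn$dW, b = dn$db)))
  } else stop("unknown block kind")
}

model_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$params))
  states <- vector("list", length(model$params))
  for (i in seq_along(model$params)) {
    bf <- block_forward(model$spec$blocks[[i]], model$params[[i]], x,
                        training)
    x <- bf$out
    caches[[i]] <- bf$cache
    states[[i]] <- bf$state
  }
  list(logits = x, caches = caches, states = states)
}

model_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$params))
  dout <- dlogits
  for (i in rev(seq_along(model$params))) {
    bb <- block_backward(model$spec$blocks[[i]], model$params[[i]],
                         caches[[i]], dout)
    grads[[i]] <- bb$grads
    dout <- bb$dx
  }
  grads
}

# write updated batch-norm running statistics back into the model
commit_bn_states <- function(model, states) {
  for (i in seq_along(states)) {
    st <- states[[i]]
    if (is.null(st)) next
    for (nm in names(st)) {
      if (is.null(st[[nm]])) next
      model$params[[i]][[nm]]$mean <- st[[nm]]$mean
      model$params[[i]][[nm]]$var <- st[[nm]]$var
    }
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
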
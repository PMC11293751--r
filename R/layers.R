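# Low-level tensor primitives for the CNN.
#
# Activations are 4-D arrays dim c(H, W, C, N) (height, width, channels,
# batch). Convolution is im2col + BLAS matmul; the column matrix has row
# order (spatial position, then sample) and column order (kernel offset,
# then input channel), so weights are stored as a (k*k*Cin) x Cout matrix.

# pad sizes for 'same' output with stride s (TensorFlow convention)
same_pad <- function(n, k, s) {
  out <- ceiling(n / s)
  total <- max(0L, (out - 1L) * s + k - n)
  c(floor(total / 2), total - floor(total / 2))
}

pad4 <- function(x, pt, pb, pl, pr, value = 0) {
  d <- dim(x)
  if (pt + pb + pl + pr == 0L) return(x)
  out <- array(value, dim = c(d[1] + pt + pb, d[2] + pl + pr, d[3], d[4]))
  out[(pt + 1):(pt + d[1]), (pl + 1):(pl + d[2]), , ] <- x
  out
}

# spatial index template: (Ho*Wo) x (k*k) linear indices into one padded
# H x W plane
im2col_template <- function(Hp, Wp, k, s) {
  r0 <- seq.int(1L, Hp - k + 1L, by = s)
  c0 <- seq.int(1L, Wp - k + 1L, by = s)
  Ho <- length(r0); Wo <- length(c0)
  pos_r <- rep(r0, times = Wo)
  pos_c <- rep(c0, each = Ho)
  off_r <- rep(seq_len(k) - 1L, times = k)
  off_c <- rep(seq_len(k) - 1L, each = k)
  idx <- outer(pos_r, off_r, `+`) + (outer(pos_c, off_c, `+`) - 1L) * Hp
  list(idx = idx, Ho = Ho, Wo = Wo)
}

# x: (H,W,C,N) padded already; returns ((Ho*Wo*N) x (k*k*C)) matrix
im2col <- function(xp, k, s) {
  d <- dim(xp)
  Hp <- d[1]; Wp <- d[2]; C <- d[3]; N <- d[4]
  tpl <- im2col_template(Hp, Wp, k, s)
  P <- tpl$idx
  npos <- nrow(P); kk <- ncol(P)
  xflat <- as.vector(xp)
  M <- matrix(0, npos * N, kk * C)
  plane <- Hp * Wp
  for (c in seq_len(C)) {
    offs <- ((c - 1L) + (seq_len(N) - 1L) * C) * plane
    idx <- rep(as.vector(P), times = N) +
      rep(offs, each = npos * kk)
    A <- array(xflat[idx], dim = c(npos, kk, N))
    M[, ((c - 1L) * kk + 1L):(c * kk)] <-
      matrix(aperm(A, c(1, 3, 2)), npos * N, kk)
  }
  list(M = M, Ho = tpl$Ho, Wo = tpl$Wo, tpl = P, dims = d, k = k, s = s)
}

# scatter-add the column gradient back into the padded input
col2im <- function(dM, cache) {
  d <- cache$dims
  Hp <- d[1]; Wp <- d[2]; C <- d[3]; N <- d[4]
  P <- cache$tpl
  npos <- nrow(P); kk <- ncol(P)
  dx <- numeric(Hp * Wp * C * N)
  plane <- Hp * Wp
  for (c in seq_len(C)) {
    block <- dM[, ((c - 1L) * kk + 1L):(c * kk), drop = FALSE]
    for (j in seq_len(kk)) {
      # rows of block are ordered (pos, n); indices within one (offset,
      # channel, sample) slice are distinct, so += is safe
      colv <- block[, j]
      for (n in seq_len(N)) {
        off <- ((c - 1L) + (n - 1L) * C) * plane
        rows <- ((n - 1L) * npos + 1L):(n * npos)
        tgt <- P[, j] + off
        dx[tgt] <- dx[tgt] + colv[rows]
      }
    }
  }
  array(dx, dim = d)
}

conv_forward <- function(x, W, b, k, stride, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  d <- dim(x)
  if (padding == "same") {
    pv <- same_pad(d[1], k, stride); ph <- same_pad(d[2], k, stride)
  } else {
    pv <- c(0L, 0L); ph <- c(0L, 0L)
  }
  xp <- pad4(x, pv[1], pv[2], ph[1], ph[2])
  cc <- im2col(xp, k, stride)
  Y <- cc$M %*% W
  if (!is.null(b)) Y <- sweep(Y, 2L, b, `+`)
  Fo <- ncol(W)
  out <- aperm(array(Y, dim = c(cc$Ho, cc$Wo, d[4], Fo)), c(1, 2, 4, 3))
  list(out = out, cache = list(col = cc, W = W, has_b = !is.null(b),
                               pad = c(pv, ph), in_dim = d))
}

conv_backward <- function(dout, cache) {
  cc <- cache$col
  d4 <- dim(dout)  # (Ho, Wo, F, N)
  dY <- matrix(aperm(dout, c(1, 2, 4, 3)), nrow = d4[1] * d4[2] * d4[4])
  dW <- crossprod(cc$M, dY)
  db <- if (cache$has_b) colSums(dY) else NULL
  dM <- tcrossprod(dY, cache$W)
  dxp <- col2im(dM, cc)
  p <- cache$pad
  di <- cache$in_dim
  dx <- dxp[(p[1] + 1):(p[1] + di[1]), (p[3] + 1):(p[3] + di[2]), , ,
            drop = FALSE]
  dim(dx) <- di
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = mask)
}

relu_backward <- function(dout, mask) {
  dout[!mask] <- 0
  dout
}

# batch normalization over (H, W, N) per channel
bn_forward <- function(x, gamma, beta, state, training, momentum = 0.9,
                       eps = 1e-5) {
  d <- dim(x)
  C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)  # rows: H*W*N
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    var <- colMeans(xc^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * var
  } else {
    mu <- state$mean; var <- state$var
    xc <- sweep(xm, 2L, mu)
  }
  inv <- 1 / sqrt(var + eps)
  xhat <- sweep(xc, 2L, inv, `*`)
  ym <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  out <- aperm(array(ym, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = out, state = state,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d))
}

bn_backward <- function(dout, cache) {
  d <- cache$d
  C <- d[3]
  dym <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = C)
  m <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, cache$gamma, `*`)
  # standard batch-norm gradient
  dxm <- sweep(dxhat - matrix(dbeta0 <- colMeans(dxhat), m, C,
                              byrow = TRUE) -
                 cache$xhat * matrix(colMeans(dxhat * cache$xhat), m, C,
                                     byrow = TRUE),
               2L, cache$inv, `*`)
  dx <- aperm(array(dxm, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  dx
}

maxpool_forward <- function(x, k, stride) {
  d <- dim(x)
  pv <- same_pad(d[1], k, stride); ph <- same_pad(d[2], k, stride)
  xp <- pad4(x, pv[1], pv[2], ph[1], ph[2], value = -Inf)
  dp <- dim(xp)
  tpl <- im2col_template(dp[1], dp[2], k, stride)
  P <- tpl$idx
  npos <- nrow(P)
  plane <- dp[1] * dp[2]
  xflat <- as.vector(xp)
  out <- array(0, dim = c(tpl$Ho, tpl$Wo, d[3], d[4]))
  arg <- array(0L, dim = c(npos, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    off <- ((c - 1L) + (n - 1L) * d[3]) * plane
    V <- matrix(xflat[as.vector(P) + off], npos, ncol(P))
    w <- max.col(V, ties.method = "first")
    arg[, c, n] <- P[cbind(seq_len(npos), w)] + off
    out[, , c, n] <- matrix(V[cbind(seq_len(npos), w)], tpl$Ho, tpl$Wo)
  }
  list(out = out, cache = list(arg = arg, dims_pad = dp, pad = c(pv, ph),
                               in_dim = d))
}

maxpool_backward <- function(dout, cache) {
  dp <- cache$dims_pad
  dxp <- numeric(prod(dp))
  d4 <- dim(dout)
  for (n in seq_len(d4[4])) for (c in seq_len(d4[3])) {
    tgt <- cache$arg[, c, n]
    g <- as.vector(dout[, , c, n])
    # overlapping windows can share an argmax: accumulate duplicates
    acc <- rowsum(g, tgt)
    ui <- as.integer(rownames(acc))
    dxp[ui] <- dxp[ui] + acc[, 1]
  }
  dxp <- array(dxp, dim = dp)
  p <- cache$pad; di <- cache$in_dim
  dx <- dxp[(p[1] + 1):(p[1] + di[1]), (p[3] + 1):(p[3] + di[2]), , ,
            drop = FALSE]
  dim(dx) <- di
  dx
}

avgpool_forward <- function(x, k, stride) {
  d <- dim(x)
  tpl <- im2col_template(d[1], d[2], k, stride)
  P <- tpl$idx
  npos <- nrow(P)
  plane <- d[1] * d[2]
  xflat <- as.vector(x)
  out <- array(0, dim = c(tpl$Ho, tpl$Wo, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    off <- ((c - 1L) + (n - 1L) * d[3]) * plane
    V <- matrix(xflat[as.vector(P) + off], npos, ncol(P))
    out[, , c, n] <- matrix(rowMeans(V), tpl$Ho, tpl$Wo)
  }
  list(out = out, cache = list(tpl = P, in_dim = d, k = k))
}

avgpool_backward <- function(dout, cache) {
  di <- cache$in_dim
  P <- cache$tpl
  dx <- numeric(prod(di))
  plane <- di[1] * di[2]
  d4 <- dim(dout)
  kk <- ncol(P)
  for (n in seq_len(d4[4])) for (c in seq_len(d4[3])) {
    off <- ((c - 1L) + (n - 1L) * di[3]) * plane
    g <- as.vector(dout[, , c, n]) / kk
    for (j in seq_len(kk)) {
      tgt <- P[, j] + off
      dx[tgt] <- dx[tgt] + g
    }
  }
  array(dx, dim = di)
}

# flatten (H,W,C per sample) and apply a dense layer
dense_forward <- function(x, W, b) {
  d <- dim(x)
  X <- t(matrix(x, nrow = prod(d[1:3])))  # N x P
  Y <- X %*% W
  Y <- sweep(Y, 2L, b, `+`)
  list(out = Y, cache = list(X = X, W = W, in_dim = d))
}

dense_backward <- function(dY, cache) {
  dW <- crossprod(cache$X, dY)
  db <- colSums(dY)
  dX <- tcrossprod(dY, cache$W)
  dx <- array(t(dX), dim = cache$in_dim)
  list(dx = dx, dW = dW, db = db)
}

# softmax probabilities (rows) and cross-entropy loss/gradient
softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_xent <- function(logits, y_onehot) {
  p <- softmax_probs(logits)
  n <- nrow(logits)
  loss <- -sum(y_onehot * log(pmax(p, 1e-12))) / n
  list(loss = loss, probs = p, dlogits = (p - y_onehot) / n)
}
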
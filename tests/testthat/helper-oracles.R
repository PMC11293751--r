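# Independent brute-force oracles, deliberately written with plain loops and
# none of the package's cumulative-sum / FFT machinery.

# direct-summation Tsallis total entropy (Eqs with sentinel boundaries)
brute_tsallis <- function(probs, thresholds, gamma) {
  b <- c(-1L, sort(as.integer(thresholds)), 255L)
  total <- 0
  for (i in seq_len(length(thresholds) + 1L)) {
    ks <- (b[i] + 1L):b[i + 1L]
    if (b[i + 1L] < b[i] + 1L) next
    p <- probs[ks + 1L]
    P <- sum(p)
    if (P <= 0) next
    inner <- sum((p[p > 0] / P)^gamma)
    total <- total + (1 - inner) / (gamma - 1)
  }
  total
}

brute_shannon <- function(probs, thresholds) {
  b <- c(-1L, sort(as.integer(thresholds)), 255L)
  total <- 0
  for (i in seq_len(length(thresholds) + 1L)) {
    ks <- (b[i] + 1L):b[i + 1L]
    p <- probs[ks + 1L]
    P <- sum(p)
    if (P <= 0) next
    q <- p[p > 0] / P
    total <- total - sum(q * log(q))
  }
  total
}

# exhaustive search over all sorted integer threshold tuples; the package's
# objective is the shared functional, the *search* routes differ
exhaustive_best_objective <- function(hist, m, gamma) {
  cand <- if (m == 1L) matrix(1:254, ncol = 1L) else
    t(utils::combn(1:254, m))
  vals <- apply(cand, 1L, function(tv)
    tsallis_objective(hist, tv, tsallis_params(gamma, m)))
  max(vals)
}

# nested-loop binary erosion / dilation / opening with zero padding
brute_erode <- function(px, fp) {
  r <- (nrow(fp) - 1L) / 2L
  h <- nrow(px); w <- ncol(px)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ok <- TRUE
    for (di in -r:r) {
      for (dj in -r:r) {
        if (!fp[di + r + 1L, dj + r + 1L]) next
        ii <- i + di; jj <- j + dj
        v <- if (ii >= 1L && ii <= h && jj >= 1L && jj <= w) px[ii, jj]
             else FALSE
        if (!v) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    out[i, j] <- ok
  }
  out
}

brute_dilate <- function(px, fp) {
  r <- (nrow(fp) - 1L) / 2L
  h <- nrow(px); w <- ncol(px)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    hit <- FALSE
    for (di in -r:r) {
      for (dj in -r:r) {
        if (!fp[di + r + 1L, dj + r + 1L]) next
        ii <- i + di; jj <- j + dj
        v <- if (ii >= 1L && ii <= h && jj >= 1L && jj <= w) px[ii, jj]
             else FALSE
        if (v) { hit <- TRUE; break }
      }
      if (hit) break
    }
    out[i, j] <- hit
  }
  out
}

brute_opening <- function(px, fp) brute_dilate(brute_erode(px, fp), fp)

# random blobby test mask: union of a few random rectangles and disks
random_mask <- function(h = 48L, w = 48L) {
  px <- matrix(FALSE, h, w)
  for (k in seq_len(sample(1:4, 1))) {
    if (stats::runif(1) < 0.5) {
      r0 <- sample(h, 1); c0 <- sample(w, 1)
      r1 <- min(h, r0 + sample(3:12, 1)); c1 <- min(w, c0 + sample(3:12, 1))
      px[r0:r1, c0:c1] <- TRUE
    } else {
      cy <- sample(h, 1); cx <- sample(w, 1); rad <- sample(2:8, 1)
      for (i in max(1, cy - rad):min(h, cy + rad))
        for (j in max(1, cx - rad):min(w, cx + rad))
          if ((i - cy)^2 + (j - cx)^2 <= rad^2) px[i, j] <- TRUE
    }
  }
  px
}

# tiny separable two-class image set: smooth bright blob vs plain noise
blob_dataset <- function(n_pos, n_neg, size = 32L, seed = 1L) {
  imgs <- list(); labels <- character(0)
  set.seed(seed)
  for (i in seq_len(n_pos + n_neg)) {
    p <- matrix(stats::runif(size * size, 0.05, 0.25), size, size)
    if (i <= n_pos) {
      cy <- size / 2 + sample(-4:4, 1); cx <- size / 2 + sample(-4:4, 1)
      d2 <- (row(p) - cy)^2 + (col(p) - cx)^2
      p[d2 <= (size / 5)^2] <- 0.9
    }
    imgs[[i]] <- gray_image(p)
    labels <- c(labels, if (i <= n_pos) "abnormal" else "normal")
  }
  mri_dataset(labels, images = imgs)
}
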
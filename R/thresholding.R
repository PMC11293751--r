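#' Tsallis entropy parameters
#'
#' @param gamma entropy index, a real value different from 1. Values below 1
#'   weight rare gray levels more heavily (sub-extensive); values above 1
#'   emphasize dominant levels. Default 0.5.
#' @param m number of thresholds, `1 <= m <= 254`.
#' @return An object of class `tsallis_params`.
#' @export
tsallis_params <- function(gamma = 0.5, m = 6L) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma))
    stop("'gamma' must be a single real value", call. = FALSE)
  if (gamma == 1)
    stop("gamma = 1 is the Shannon limit; use shannon_limit() instead",
         call. = FALSE)
  m <- as.integer(m)
  if (m < 1L || m > 254L) stop("require 1 <= m <= 254", call. = FALSE)
  structure(list(gamma = gamma, m = m), class = "tsallis_params")
}

#' Threshold vector
#'
#' Sorted integer gray-level thresholds with the objective value attained
#' and, once computed, the aggregate threshold `T_a`.
#'
#' @param values integer thresholds in `[1, 254]`, sorted non-decreasing.
#' @param objective total Tsallis entropy at these thresholds.
#' @param aggregate optional aggregate threshold.
#' @param trace optional numeric vector of best-so-far objective by
#'   generation (populated by [optimize_thresholds()]).
#' @return An object of class `threshold_vector`.
#' @export
threshold_vector <- function(values, objective = NA_real_, aggregate = NULL,
                             trace = NULL) {
  values <- as.integer(round(values))
  if (any(values < 1L) || any(values > 254L))
    stop("thresholds must lie in [1, 254]", call. = FALSE)
  values <- sort(values)
  structure(list(values = values, objective = objective,
                 aggregate = aggregate, trace = trace),
            class = "threshold_vector")
}

#' @export
print.threshold_vector <- function(x, ...) {
  cat(sprintf("<threshold_vector m=%d: %s | objective %.6g%s>\n",
              length(x$values), paste(x$values, collapse = ", "),
              x$objective,
              if (is.null(x$aggregate)) ""
              else sprintf(" | T_a %.3f", x$aggregate)))
  invisible(x)
}

# cumulative sums used by both entropy functionals; index i+1 holds the sum
# over gray levels 0..i-1
entropy_tables <- function(h, gamma) {
  pos <- h > 0
  hg <- numeric(256L); hg[pos] <- h[pos]^gamma
  hl <- numeric(256L); hl[pos] <- h[pos] * log(h[pos])
  list(S1 = c(0, cumsum(h)), Sg = c(0, cumsum(hg)), Sl = c(0, cumsum(hl)))
}

# total entropy over classes delimited by integer thresholds, vectorized over
# a population: Tm is an (n x m) matrix of sorted integer thresholds
tsallis_total <- function(tab, Tm, gamma, pseudo_additive = FALSE) {
  n <- nrow(Tm); m <- ncol(Tm)
  lo <- cbind(rep(0L, n), Tm + 1L)       # class i spans lo[,i] .. hi[,i]
  hi <- cbind(Tm, rep(255L, n))
  total <- numeric(n)
  prod_term <- if (pseudo_additive) rep(1, n) else NULL
  for (i in seq_len(m + 1L)) {
    P <- tab$S1[hi[, i] + 2L] - tab$S1[lo[, i] + 1L]
    G <- tab$Sg[hi[, i] + 2L] - tab$Sg[lo[, i] + 1L]
    Hi <- numeric(n)
    ok <- P > 0
    Hi[ok] <- (1 - G[ok] / P[ok]^gamma) / (gamma - 1)
    total <- total + Hi
    if (pseudo_additive) prod_term <- prod_term * Hi
  }
  if (pseudo_additive) total <- total + (1 - gamma) * prod_term
  total
}

#' Total Tsallis entropy of a thresholded histogram
#'
#' Partitions the 256 gray levels into `m + 1` classes, class `i` spanning
#' levels `(t[i-1], t[i]]` with sentinels `t[0] = -1` and `t[m+1] = 255`,
#' and returns the sum of per-class Tsallis entropies
#' `H_i = (1 - sum_k (h_k / P_i)^gamma) / (gamma - 1)`, where `P_i` is the
#' class probability mass. Empty classes and zero-probability bins
#' contribute nothing. The objective depends only on the normalized
#' histogram, never on raw counts.
#'
#' @param hist a [gray_histogram()], [gray_image()] or probability vector.
#' @param thresholds integer thresholds in `[1, 254]` (any order; sorted
#'   internally), or a [threshold_vector()].
#' @param params a [tsallis_params()]; `m` is taken from `thresholds`.
#' @param pseudo_additive when `TRUE`, adds the Tsallis composition cross
#'   term `(1 - gamma) * prod(H_i)` to the plain sum. Default `FALSE`.
#' @return The total entropy, a single real value.
#' @export
tsallis_objective <- function(hist, thresholds, params = tsallis_params(),
                              pseudo_additive = FALSE) {
  h <- as_histogram(hist)$probs
  tv <- if (inherits(thresholds, "threshold_vector")) thresholds$values
        else as.integer(round(thresholds))
  if (any(tv < 1L) || any(tv > 254L))
    stop("thresholds must lie in [1, 254]", call. = FALSE)
  tv <- sort(tv)
  tab <- entropy_tables(h, params$gamma)
  tsallis_total(tab, matrix(tv, nrow = 1), params$gamma, pseudo_additive)
}

#' Shannon limit of the thresholding objective
#'
#' The gamma -> 1 limit of [tsallis_objective()]: the sum over classes of
#' the Shannon entropy of the within-class distribution,
#' `sum_i -sum_k (h_k/P_i) log(h_k/P_i)` (natural log). Used as the
#' independent oracle for the Tsallis functional near gamma = 1.
#'
#' @inheritParams tsallis_objective
#' @return The total Shannon entropy, a single real value.
#' @export
shannon_limit <- function(hist, thresholds) {
  h <- as_histogram(hist)$probs
  tv <- sort(as.integer(round(
    if (inherits(thresholds, "threshold_vector")) thresholds$values
    else thresholds)))
  tab <- entropy_tables(h, gamma = 1)  # gamma unused for S1/Sl
  b <- c(-1L, tv, 255L)
  total <- 0
  for (i in seq_len(length(tv) + 1L)) {
    lo <- b[i] + 1L; hi <- b[i + 1L]
    if (hi < lo) next
    P <- tab$S1[hi + 2L] - tab$S1[lo + 1L]
    if (P <= 0) next
    HL <- tab$Sl[hi + 2L] - tab$Sl[lo + 1L]  # sum h log h
    total <- total - HL / P + log(P)
  }
  total
}

#' Differential evolution configuration
#'
#' DE/rand/1/bin defaults: one gene per threshold (`D = m`), population
#' `NP = 10 D`, weighting factor `F = 0.5`, crossover rate `CR = 0.9`,
#' at most 100 generations, genes bounded in `[1, 254]`. Early stopping on
#' a stagnant best objective is available via `stall_generations` but is
#' disabled by default (aggressive stalling measurably costs optimality on
#' sparse histograms).
#'
#' @param D genome length (number of thresholds).
#' @param NP population size, at least 4.
#' @param F mutation weighting factor, positive.
#' @param CR crossover probability in `[0, 1]`.
#' @param generations maximum generations.
#' @param stall_generations early stop after this many generations without
#'   improvement of the best objective (> 1e-12).
#' @param seed integer RNG seed.
#' @return An object of class `de_config`.
#' @export
de_config <- function(D = 6L, NP = 10L * as.integer(D), F = 0.5, CR = 0.9,
                      generations = 100L, stall_generations = generations,
                      seed = 17L) {
  D <- as.integer(D); NP <- as.integer(NP)
  if (NP < 4L)
    stop("'NP' must be >= 4 (mutation draws 3 distinct non-target indices)",
         call. = FALSE)
  if (F <= 0) stop("'F' must be positive", call. = FALSE)
  if (CR < 0 || CR > 1) stop("'CR' must lie in [0, 1]", call. = FALSE)
  structure(list(D = D, NP = NP, F = F, CR = CR,
                 generations = as.integer(generations),
                 stall_generations = as.integer(stall_generations),
                 seed = as.integer(seed), bounds = c(1, 254)),
            class = "de_config")
}

#' Maximize the Tsallis objective by differential evolution
#'
#' DE/rand/1/bin: `NP` real genomes initialized uniformly in `[1, 254]`;
#' each generation builds, for every target `x`, a mutant
#' `v = x_r1 + F (x_r2 - x_r3)` from three distinct random non-target rows,
#' reflects out-of-bound genes back into range, applies binomial crossover
#' at rate `CR` with one
#' guaranteed mutant gene, and keeps whichever of target and trial scores
#' the higher objective (ties go to the trial). Genomes are sorted and
#' rounded to integers for objective evaluation only; the search itself is
#' real-valued. The best-so-far objective is non-decreasing and the whole
#' run is deterministic under the configured seed.
#'
#' @param hist a [gray_histogram()], [gray_image()] or probability vector.
#' @param params a [tsallis_params()]; its `m` sets the genome length unless
#'   `de_cfg` overrides `D`.
#' @param de_cfg a [de_config()].
#' @param pseudo_additive passed to the objective.
#' @return A [threshold_vector()] with the best thresholds, their objective
#'   and the per-generation best-so-far `trace`.
#' @export
optimize_thresholds <- function(hist, params = tsallis_params(),
                                de_cfg = de_config(D = params$m),
                                pseudo_additive = FALSE) {
  h <- as_histogram(hist)$probs
  gamma <- params$gamma
  D <- de_cfg$D; NP <- de_cfg$NP
  lo <- de_cfg$bounds[1]; hi <- de_cfg$bounds[2]
  tab <- entropy_tables(h, gamma)
  evaluate <- function(X) {
    # sort rows, round to integers, clip, then score
    Xi <- t(apply(X, 1L, sort))
    if (D == 1L) Xi <- matrix(Xi, ncol = 1L)
    Xi <- matrix(as.integer(pmin(pmax(round(Xi), lo), hi)), nrow = nrow(X))
    tsallis_total(tab, Xi, gamma, pseudo_additive)
  }
  with_seed(de_cfg$seed, {
    X <- matrix(stats::runif(NP * D, lo, hi), NP, D)
    fx <- evaluate(X)
    best_trace <- numeric(0)
    stall <- 0L
    best_prev <- max(fx)
    for (g in seq_len(de_cfg$generations)) {
      idx <- vapply(seq_len(NP), function(i)
        sample(setdiff(seq_len(NP), i), 3L), integer(3))
      V <- X[idx[1, ], , drop = FALSE] +
        de_cfg$F * (X[idx[2, ], , drop = FALSE] - X[idx[3, ], , drop = FALSE])
      # reflect out-of-bound genes back into range (clipping piles genomes
      # onto the bound and stalls the search on bound-adjacent optima)
      V <- ifelse(V < lo, 2 * lo - V, V)
      V <- ifelse(V > hi, 2 * hi - V, V)
      V <- pmin(pmax(V, lo), hi)
      cross <- matrix(stats::runif(NP * D) < de_cfg$CR, NP, D)
      jrand <- sample.int(D, NP, replace = TRUE)
      cross[cbind(seq_len(NP), jrand)] <- TRUE
      U <- ifelse(cross, V, X)
      fu <- evaluate(U)
      take <- fu >= fx
      X[take, ] <- U[take, , drop = FALSE]
      fx[take] <- fu[take]
      best <- max(fx)
      best_trace <- c(best_trace, best)
      if (best - best_prev < 1e-12) stall <- stall + 1L else stall <- 0L
      best_prev <- best
      if (stall >= de_cfg$stall_generations) break
    }
    ib <- which.max(fx)
    vals <- sort(as.integer(pmin(pmax(round(X[ib, ]), lo), hi)))
    threshold_vector(vals, objective = fx[ib], trace = best_trace)
  })
}

#' Aggregate threshold: mean of the three largest thresholds
#'
#' Multiset semantics: the three entries at the top of the descending-sorted
#' threshold list are averaged, duplicates included.
#'
#' @param tv a [threshold_vector()] or integer vector with at least three
#'   entries.
#' @return The aggregate threshold `T_a`, a single real value.
#' @export
aggregate_threshold <- function(tv) {
  vals <- if (inherits(tv, "threshold_vector")) tv$values else
    as.numeric(tv)
  if (length(vals) < 3L)
    stop("aggregation needs at least 3 thresholds", call. = FALSE)
  mean(sort(vals, decreasing = TRUE)[1:3])
}

#' Binarize an image at an aggregate threshold
#'
#' Foreground (the hyperintense tumor-candidate region) is every pixel whose
#' 256-level quantized intensity is strictly greater than `T_a`.
#'
#' @param img a [gray_image()] or numeric matrix in `[0, 1]`.
#' @param t_a aggregate threshold on the 0...255 gray-level scale.
#' @return A [binary_mask()] with role `"segmentation"`.
#' @export
binarize <- function(img, t_a) {
  q <- quantize(img, 256L)
  binary_mask(q > t_a, role = "segmentation")
}
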
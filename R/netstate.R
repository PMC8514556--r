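#' Sliding-window directed coupling scores
#'
#' Splits a multichannel recording into contiguous epochs, slides a window
#' across each epoch, and computes every directed pairwise coupling score
#' within each window. With 3 channels each window yields a 6-dimensional
#' directed score vector, the representation used for the network-state
#' analysis. Defaults mirror an LFP-style setup: 1 s epochs, 400 ms windows,
#' 3 windows tiling the epoch (in samples: `epochLen = 500`,
#' `windowLen = 200` at 500 Hz).
#'
#' @param series a [TimeSeries-class] (3 channels for the canonical
#'   6-dimensional state space).
#' @param epochLen epoch length in samples.
#' @param windowLen window length in samples.
#' @param step window step in samples; default tiles the epoch with 3
#'   windows, `floor((epochLen - windowLen)/2)`.
#' @param params shared [EmbeddingParams-class] for all windows.
#' @param epochLabels optional condition tag per epoch.
#' @param method `"CCS"` (default) or `"CCM"`.
#' @param ... passed to [scoreAllPairs()].
#' @return A [WindowedScores-class].
#' @export
windowedCCS <- function(series, epochLen, windowLen, step = NULL,
                        params = EmbeddingParams(3L, 2L),
                        epochLabels = NULL, method = "CCS", ...) {
  if (windowLen > epochLen) stop("epoch must be at least one window long")
  minLen <- (embeddingDim(params) - 1L) * embeddingLag(params) +
    embeddingDim(params) * embeddingLag(params) + 2L
  if (windowLen < minLen)
    stop(sprintf(
      "window too short for embedding: need at least %d samples for dim %d, lag %d",
      minLen, embeddingDim(params), embeddingLag(params)), call. = FALSE)
  if (is.null(step))
    step <- max(1L, as.integer(floor((epochLen - windowLen) / 2)))
  v <- tsValues(series)
  nEpochs <- nrow(v) %/% epochLen
  if (nEpochs < 1L) stop("series shorter than one epoch")
  starts <- seq(1L, epochLen - windowLen + 1L, by = step)
  nW <- length(starts)
  labs <- channelNames(series)
  pairNames <- directedPairNames(labs)
  scores <- array(NA_real_, c(nEpochs, nW, length(pairNames)))
  for (e in seq_len(nEpochs)) {
    off <- (e - 1L) * epochLen
    for (w in seq_len(nW)) {
      seg <- v[off + starts[w] + 0:(windowLen - 1L), , drop = FALSE]
      sc <- scoreAllPairs(TimeSeries(seg, dt = samplingInterval(series),
                                     labels = labs),
                          method = method, params = params, ...)
      scores[e, w, ] <- sc$score[match(
        pairNames, paste0(sc$source, "->", sc$target))]
    }
  }
  if (is.null(epochLabels)) epochLabels <- rep("all", nEpochs)
  new("WindowedScores", scores = scores, windowLen = as.integer(windowLen),
      stepLen = as.integer(step), epochLabels = rep_len(epochLabels, nEpochs),
      pairNames = pairNames)
}

#' Quantize windowed scores into network states with k-means
#'
#' Scores are standardized and whitened (principal components scaled to
#' unit variance), clustered by seeded k-means with multiple restarts in the
#' full whitened space (the 2-component projection is for display only),
#' and every window is assigned a state label in 1..k. Centroids are
#' back-transformed through the whitening and standardization so they read
#' in raw score units.
#'
#' @param ws a [WindowedScores-class].
#' @param k number of states (default 5).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts (default 25).
#' @return A list: `states` (a [StateSequences-class]), `centroids`
#'   (k x pairs, raw score units), `whitenedCentroids`, `projection`
#'   (windows x 2 first principal components), `assignments` (vector over
#'   flattened windows), and `fit` (the kmeans object).
#' @export
clusterStates <- function(ws, k = 5L, seed = 1L, nstart = 25L) {
  d <- dim(ws@scores)
  flat <- matrix(ws@scores, d[1L] * d[2L], d[3L])  # epoch-major flattening
  if (k < 2L) stop("k must be at least 2")
  if (k > nrow(flat)) stop("k exceeds the number of windows")
  ctr <- colMeans(flat)
  scl <- apply(flat, 2L, sd)
  scl[scl == 0] <- 1
  std <- sweep(sweep(flat, 2L, ctr), 2L, scl, "/")
  pca <- prcomp(std, center = FALSE, scale. = FALSE)
  nPC <- sum(pca$sdev > 1e-10)
  white <- pca$x[, seq_len(nPC), drop = FALSE] %*%
    diag(1 / pca$sdev[seq_len(nPC)], nPC)
  fit <- withSeed(seed, kmeans(white, centers = k, nstart = nstart,
                               iter.max = 100L))
  # undo whitening, then standardization, to express centroids as scores
  backStd <- fit$centers %*% diag(pca$sdev[seq_len(nPC)], nPC) %*%
    t(pca$rotation[, seq_len(nPC), drop = FALSE])
  centroids <- sweep(sweep(backStd, 2L, scl, "*"), 2L, ctr, "+")
  colnames(centroids) <- ws@pairNames
  labels <- matrix(fit$cluster, d[1L], d[2L])
  list(states = new("StateSequences", labels = labels, k = as.integer(k),
                    epochLabels = ws@epochLabels),
       centroids = centroids,
       whitenedCentroids = fit$centers,
       projection = pca$x[, seq_len(min(2L, nPC)), drop = FALSE],
       assignments = fit$cluster,
       fit = fit)
}

#' Canonical form of a sequence under cyclic rotation
#'
#' Epoch phase carries no information when epochs are cut from longer
#' events, so state sequences that are cyclic rotations of one another are
#' the same pattern; the canonical representative is the lexicographically
#' smallest rotation.
#'
#' @param x integer (or character) vector.
#' @return The canonical rotation of `x`.
#' @examples
#' canonicalCycle(c(2, 3, 1))  # 1 2 3
#' @export
canonicalCycle <- function(x) {
  n <- length(x)
  if (n <= 1L) return(x)
  rots <- t(vapply(seq_len(n), function(s)
    x[((seq_len(n) + s - 2L) %% n) + 1L], x))
  best <- do.call(order, as.data.frame(rots))[1L]
  x[((seq_len(n) + best - 2L) %% n) + 1L]
}

# Number of distinct cyclic classes of length-w sequences over k symbols
# (Burnside: mean of k^gcd(w, s) over shifts s).
countCyclicClasses <- function(k, w) {
  shifts <- seq_len(w)
  g <- vapply(shifts, function(s) gcdInt(w, s), numeric(1))
  round(sum(k^g) / w)
}

gcdInt <- function(a, b) if (b == 0) a else gcdInt(b, a %% b)

#' Frequency and extremeness of network-state sequences
#'
#' Canonicalizes every epoch's state sequence under cyclic rotation,
#' tabulates pattern frequencies per condition with the standard error of
#' the percentage, and attaches to the nth most frequent pattern the
#' negative log10 of the probability that the nth most frequent pattern
#' under the null would have a frequency at least as extreme as the one
#' observed. The null draws each epoch's states independently and uniformly
#' (so a canonical class's probability is its share of the k^w raw
#' sequences, computed by enumeration when feasible). Because the
#' probability is rank-aware — the observed count of the nth pattern is
#' compared with the null distribution of the nth largest count — it is
#' estimated by Monte Carlo by default; `null = "binomial"` gives the
#' simpler per-class binomial tail instead, which ignores the selection of
#' the top pattern and is therefore anti-conservative at rank 1.
#'
#' @param states a [StateSequences-class].
#' @param null `"simulation"` (rank-aware, default) or `"binomial"`.
#' @param nSim Monte Carlo draws for the simulation null.
#' @param seed RNG seed for the simulation null.
#' @param maxPatterns report at most this many top patterns per condition.
#' @return A data.frame per condition and pattern rank: `condition`,
#'   `pattern`, `count`, `pct`, `se_pct`, `neg_log10_p`.
#' @export
sequenceStatistics <- function(states, null = c("simulation", "binomial"),
                               nSim = 1000L, seed = 1L, maxPatterns = 10L) {
  null <- match.arg(null)
  labm <- stateLabels(states)
  w <- ncol(labm)
  probs <- cyclicClassProbs(states@k, w)
  canon <- apply(labm, 1L, function(s)
    paste(canonicalCycle(s), collapse = "-"))
  out <- list()
  for (cond in unique(states@epochLabels)) {
    idx <- states@epochLabels == cond
    n <- sum(idx)
    if (n == 0L) stop("empty condition '", cond, "'")
    tab <- sort(table(canon[idx]), decreasing = TRUE)
    top <- head(tab, maxPatterns)
    pct <- 100 * as.numeric(top) / n
    se <- 100 * sqrt((pct / 100) * (1 - pct / 100) / n)
    if (null == "binomial") {
      p <- probs[names(top)]
      p[is.na(p)] <- 1 / length(probs)
      nl <- -log10(pmax(pbinom(as.numeric(top) - 1L, n, p,
                               lower.tail = FALSE), 1e-300))
    } else {
      nl <- simulationExtremeness(as.numeric(top), n, probs, nSim, seed)
    }
    out[[length(out) + 1L]] <- data.frame(
      condition = cond, rank = seq_along(top), pattern = names(top),
      count = as.numeric(top), pct = pct, se_pct = se,
      neg_log10_p = unname(nl), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Probability of each canonical class under iid uniform states: class size
# over k^w, by enumeration (falling back to uniform classes when the raw
# sequence space is too large to enumerate).
cyclicClassProbs <- function(k, w) {
  if (k^w <= 2e5) {
    seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), w)))
    canon <- apply(seqs, 1L, function(s)
      paste(canonicalCycle(as.integer(s)), collapse = "-"))
    table(canon) / k^w
  } else {
    nC <- countCyclicClasses(k, w)
    stats::setNames(rep(1 / nC, nC), paste0("class", seq_len(nC)))
  }
}

# Rank-aware Monte Carlo null: the nth most frequent pattern's count under
# iid uniform states, compared with the observed nth count.
simulationExtremeness <- function(observedCounts, n, probs, nSim, seed) {
  m <- length(observedCounts)
  nClasses <- length(probs)
  sims <- withSeed(seed, vapply(seq_len(nSim), function(b) {
    cnt <- tabulate(sample.int(nClasses, n, replace = TRUE,
                               prob = as.numeric(probs)), nClasses)
    sort(cnt, decreasing = TRUE)[seq_len(m)]
  }, numeric(m)))
  if (m == 1L) sims <- matrix(sims, nrow = 1L)
  p <- vapply(seq_len(m), function(r)
    (1 + sum(sims[r, ] >= observedCounts[r])) / (1 + nSim), numeric(1))
  -log10(p)
}

#' Match estimated centroids to reference centroids
#'
#' Exhaustive assignment (all permutations, so k <= 8) minimizing the total
#' squared distance between matched centroid rows; used to compare recovered
#' k-means centroids with scripted ground truth.
#'
#' @param estimated,reference k x d matrices.
#' @return A list: `perm` (row i of `reference` matches row `perm[i]` of
#'   `estimated`) and `rmse` (element-wise RMSE after matching).
#' @export
matchCentroids <- function(estimated, reference) {
  k <- nrow(reference)
  if (nrow(estimated) != k) stop("centroid sets must have equal size")
  if (k > 8L) stop("exhaustive matching supports k <= 8")
  perms <- permuteAll(seq_len(k))
  best <- NULL
  bestCost <- Inf
  for (p in perms) {
    cost <- sum((reference - estimated[p, , drop = FALSE])^2)
    if (cost < bestCost) { bestCost <- cost; best <- p }
  }
  list(perm = best, rmse = sqrt(bestCost / length(reference)))
}

permuteAll <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(permuteAll(x[-i]), function(p) c(x[i], p)))
  out
}

#' Scripted windowed scores from known state centroids
#'
#' Generates a [WindowedScores-class] whose per-window score vectors are
#' drawn from scripted regimes: each window's vector is its regime's
#' centroid plus isotropic Gaussian noise. This is the synthetic
#' ground-truth generator for validating the state-clustering pipeline
#' (known centroids, known labels); it makes no claim about any real
#' recording.
#'
#' @param centroids k x d matrix of regime score vectors.
#' @param schedule integer matrix (epochs x windows) of regime indices.
#' @param noiseSd isotropic noise scale added to each vector.
#' @param seed RNG seed.
#' @param epochLabels optional condition tag per epoch.
#' @param pairNames names of the d score dimensions.
#' @return A list: `ws` (the [WindowedScores-class]) and `schedule`.
#' @export
syntheticWindowedScores <- function(centroids, schedule, noiseSd = 0.05,
                                    seed = 1L, epochLabels = NULL,
                                    pairNames = NULL) {
  centroids <- as.matrix(centroids)
  d <- ncol(centroids)
  nE <- nrow(schedule); nW <- ncol(schedule)
  if (is.null(pairNames)) pairNames <- paste0("s", seq_len(d))
  scores <- withSeed(seed, {
    arr <- array(NA_real_, c(nE, nW, d))
    for (e in seq_len(nE)) for (w in seq_len(nW))
      arr[e, w, ] <- centroids[schedule[e, w], ] + rnorm(d, 0, noiseSd)
    arr
  })
  if (is.null(epochLabels)) epochLabels <- rep("all", nE)
  list(ws = new("WindowedScores", scores = scores,
                windowLen = 1L, stepLen = 1L,
                epochLabels = rep_len(epochLabels, nE),
                pairNames = pairNames),
       schedule = schedule)
}

#' Three-channel oscillator recording with scripted coupling switches
#'
#' A synthetic stand-in for a multichannel neural recording: three Van der
#' Pol oscillators integrated continuously while the coupling matrix
#' switches between scripted regimes on a fixed segment grid. The state
#' carries across switches, so the signal is continuous; each segment's
#' regime index is returned as ground truth for windowed analyses.
#'
#' @param regimes list of 3 x 3 coupling matrices.
#' @param schedule integer vector of regime indices, one per segment.
#' @param segmentLen samples per segment.
#' @param mu per-oscillator stiffness (length 3).
#' @param noise a [NoiseSpec-class]; `dynEps` perturbs the velocities,
#'   `snrDb` adds measurement noise.
#' @param dtInt,sampleEvery integration step and downsampling factor.
#' @param burnIn discarded integration time units before the first segment.
#' @return A list: `series` (a [TimeSeries-class] of
#'   `segmentLen * length(schedule)` samples), `schedule`, `regimes`.
#' @export
regimeSwitchTriad <- function(regimes, schedule, segmentLen,
                              mu = c(1, 1.5, 2), noise = NoiseSpec(),
                              dtInt = 0.05, sampleEvery = 4L, burnIn = 100) {
  n <- 3L
  for (K in regimes)
    if (!all(dim(K) == c(3L, 3L)) || any(diag(K) != 0) || any(K < 0))
      stop("each regime must be a 3x3 nonnegative zero-diagonal matrix")
  withSeed(noise@seed, {
    x <- runif(n, -2, 2); v <- runif(n, -2, 2)
    noiseSd <- noise@dynEps * sqrt(dtInt)
    stepOnce <- function(K) {
      deriv <- function(x, v)
        list(dx = v,
             dv = mu * (1 - x^2) * v - x +
               as.numeric(crossprod(K, x)) - colSums(K) * x)
      k1 <- deriv(x, v)
      k2 <- deriv(x + dtInt / 2 * k1$dx, v + dtInt / 2 * k1$dv)
      k3 <- deriv(x + dtInt / 2 * k2$dx, v + dtInt / 2 * k2$dv)
      k4 <- deriv(x + dtInt * k3$dx, v + dtInt * k3$dv)
      x <<- x + dtInt / 6 * (k1$dx + 2 * k2$dx + 2 * k3$dx + k4$dx)
      v <<- v + dtInt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
      if (noiseSd > 0) v <<- v + rnorm(n, 0, noiseSd)
      if (any(!is.finite(x))) stop("oscillator state became non-finite")
    }
    for (s in seq_len(ceiling(burnIn / dtInt))) stepOnce(regimes[[1L]])
    out <- matrix(NA_real_, segmentLen * length(schedule), n)
    row <- 0L
    for (seg in seq_along(schedule)) {
      K <- regimes[[schedule[seg]]]
      for (smp in seq_len(segmentLen)) {
        for (ss in seq_len(sampleEvery)) stepOnce(K)
        row <- row + 1L
        out[row, ] <- x
      }
    }
    series <- TimeSeries(out, dt = dtInt * sampleEvery,
                         labels = c("OB", "CA", "AMG"))
    if (is.finite(noise@snrDb))
      series <- addMeasurementNoise(series, noise@snrDb,
                                    seed = childSeed(noise@seed, 31L))
    list(series = series, schedule = schedule, regimes = regimes)
  })
}
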
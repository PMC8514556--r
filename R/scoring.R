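# All-pairs scoring of a multichannel series. Both methods share the
# embeddings and distance structure per channel, so the 6 directed scores of
# a 3-channel trial reuse 3 distance computations instead of 12.

#' Score every directed channel pair of a multichannel series
#'
#' Computes the directed coupling score for all ordered channel pairs with a
#' shared embedding (so scores are commensurable across pairs), reusing each
#' channel's delay embedding and distance ranks across the pairs it appears
#' in. This is the workhorse behind the detection, sweep, and windowed
#' analyses.
#'
#' @param series a [TimeSeries-class] with at least 2 channels.
#' @param method `"CCS"` or `"CCM"`.
#' @param params shared [EmbeddingParams-class] (default: selected from the
#'   first channel).
#' @param exclusionWindow Theiler window (default `dim * lag`).
#' @param maxRankFrac,nullMode,maxPairs,seed CCS settings, see [ccs()].
#' @param k CCM neighbor count, see [ccm()].
#' @param normalize z-score channels before embedding (default TRUE).
#' @return A data.frame with columns `source`, `target`, `method`, `score`,
#'   `fit_ok`.
#' @export
scoreAllPairs <- function(series, method = c("CCS", "CCM"), params = NULL,
                          exclusionWindow = NULL, maxRankFrac = 0.25,
                          nullMode = "conditional", maxPairs = 2e6, seed = NULL,
                          k = NULL, normalize = TRUE) {
  method <- match.arg(method)
  if (nChannels(series) < 2L) stop("need at least 2 channels")
  if (is.null(params)) params <- selectEmbeddingParams(series)
  if (is.null(exclusionWindow))
    exclusionWindow <- embeddingDim(params) * embeddingLag(params)
  labs <- channelNames(series)
  nCh <- length(labs)
  chans <- lapply(seq_len(nCh), function(i) {
    v <- tsChannel(series, i)
    if (normalize) zScore(v) else v
  })
  embs <- lapply(chans, delayEmbed, params = params)
  if (method == "CCS") {
    ranks <- channelDistanceRanks(embs, exclusionWindow, maxPairs, seed)
    nP <- length(ranks[[1L]])
    nullMarg <- nullErr2(nP)
    score1 <- function(s, t) {
      ordT <- order(ranks[[t]])
      err <- (ranks[[s]] - ranks[[t]])[ordT]
      null <- if (nullMode == "marginal") nullMarg else
        nullErr2(nP, "conditional", rank = ranks[[t]][ordT])
      ccsScoreFromCurve(nerr2Curve(err, null), maxRankFrac)
    }
  } else {
    if (is.null(k)) k <- embeddingDim(params) + 1L
    maps <- lapply(embs, crossMapWeights, k = k,
                   exclusionWindow = exclusionWindow)
    span <- (embeddingDim(params) - 1L) * embeddingLag(params)
    score1 <- function(s, t) {
      # score(s -> t): cross-map channel s from the driven manifold M_t,
      # aligned at each vector's most recent coordinate time
      lib <- maps[[t]]
      vals <- chans[[s]][embeddingTimes(embs[[t]]) + span]
      pred <- rowSums(lib$w * matrix(vals[lib$idx], nrow(lib$idx)))
      v <- if (sd(pred) == 0 || sd(vals) == 0) {
        warning("zero-variance cross-map estimates; score defined as 0")
        0
      } else cor(pred, vals)
      list(value = max(-1, min(1, v)), fitOk = TRUE)
    }
  }
  pairs <- directedPairIndices(nCh)
  res <- lapply(seq_len(nrow(pairs)), function(p) {
    s <- pairs[p, 1L]; t <- pairs[p, 2L]
    sc <- score1(s, t)
    data.frame(source = labs[s], target = labs[t], method = method,
               score = sc$value, fit_ok = sc$fitOk,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Distance ranks per channel over a common admissible pair set.
channelDistanceRanks <- function(embs, exclusionWindow, maxPairs, seed) {
  times <- embeddingTimes(embs[[1L]])
  n <- length(times)
  pr <- pairIndexUpper(n)
  keep <- abs(times[pr[, 1L]] - times[pr[, 2L]]) > exclusionWindow
  if (sum(keep) < 2L)
    stop("fewer than 2 retained pairs after the temporal-exclusion rule",
         call. = FALSE)
  sub <- NULL
  if (sum(keep) > maxPairs)
    sub <- withSeed(seed, sort(sample.int(sum(keep), maxPairs)))
  lapply(embs, function(e) {
    d <- as.numeric(dist(embeddingPoints(e)))[keep]
    if (!is.null(sub)) d <- d[sub]
    if (all(d == 0))
      stop("degenerate input: all pairwise distances are zero in one manifold",
           call. = FALSE)
    rank(d, ties.method = "average")
  })
}

# Neighbor indices and exponential weights for every point of a library.
crossMapWeights <- function(lib, k, exclusionWindow) {
  pts <- embeddingPoints(lib)
  times <- embeddingTimes(lib)
  n <- nrow(pts)
  dm <- as.matrix(dist(pts))
  dm[abs(outer(times, times, "-")) <= exclusionWindow] <- Inf
  idx <- matrix(0L, n, k)
  w <- matrix(0, n, k)
  for (t in seq_len(n)) {
    d <- dm[t, ]
    ord <- order(d)[seq_len(k)]
    dnn <- d[ord]
    if (!is.finite(dnn[k]))
      stop(sprintf("only %d admissible neighbors, need %d",
                   sum(is.finite(d)), k), call. = FALSE)
    wt <- if (dnn[1L] == 0) as.numeric(dnn == 0) else exp(-dnn / dnn[1L])
    idx[t, ] <- ord
    w[t, ] <- wt / sum(wt)
  }
  list(idx = idx, w = w)
}
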
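#' Delay-coordinate embedding of a scalar time series
#'
#' Builds the delay reconstruction of the attractor from one observed
#' channel: row i of the returned point matrix is
#' `c(x[i], x[i + lag], ..., x[i + (D-1) lag])`, for
#' `i = 1 .. L - (D-1) lag`. By Takens' theorem this point cloud is (for
#' suitable D and lag) homeomorphic to the attractor of the full system,
#' which is what the coupling statistics exploit. No normalization is applied
#' here; callers that want commensurable distance scales z-score first.
#'
#' @param series a [TimeSeries-class], or a numeric vector.
#' @param params an [EmbeddingParams-class] (dimension D and lag tau).
#' @param channel channel index or name when `series` is multichannel.
#' @return A [DelayEmbedding-class] with `L - (D-1) lag` points in temporal
#'   order.
#' @examples
#' emb <- delayEmbed(TimeSeries(1:5), EmbeddingParams(dim = 2, lag = 1))
#' embeddingPoints(emb)
#' @export
delayEmbed <- function(series, params, channel = 1L) {
  x <- if (is(series, "TimeSeries")) tsChannel(series, channel)
       else as.numeric(series)
  D <- embeddingDim(params)
  tau <- embeddingLag(params)
  L <- length(x)
  span <- (D - 1L) * tau
  if (span >= L)
    stop(sprintf(
      "series too short to embed: need length > (dim-1)*lag = %d, got %d",
      span, L), call. = FALSE)
  n <- L - span
  pts <- vapply(seq_len(D) - 1L,
                function(d) x[seq_len(n) + d * tau], numeric(n))
  if (n == 1L) pts <- matrix(pts, nrow = 1L)
  new("DelayEmbedding", points = unname(pts), times = seq_len(n),
      params = params)
}

# Binned mutual information between x[t] and x[t + lag].
laggedMutualInformation <- function(x, lag, nBins = 16L) {
  n <- length(x) - lag
  a <- x[seq_len(n)]
  b <- x[seq_len(n) + lag]
  br <- seq(min(x), max(x), length.out = nBins + 1L)
  ia <- findInterval(a, br, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(b, br, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(ia, ib) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}

# Fraction of false nearest neighbors at dimension D (Kennel criterion).
falseNeighborFraction <- function(x, D, lag, rTol = 10, aTol = 2) {
  emb <- delayEmbed(x, EmbeddingParams(D, lag))
  pts <- embeddingPoints(emb)
  # only points whose (D+1)-th coordinate exists can be tested
  nUse <- length(x) - D * lag
  if (nUse < 2L) return(NA_real_)
  pts <- pts[seq_len(nUse), , drop = FALSE]
  dm <- as.matrix(dist(pts))
  diag(dm) <- Inf
  nn <- apply(dm, 1L, which.min)
  dNN <- dm[cbind(seq_len(nUse), nn)]
  extra <- abs(x[seq_len(nUse) + D * lag] - x[nn + D * lag])
  sigma <- sd(x)
  false1 <- extra / pmax(dNN, .Machine$double.eps) > rTol
  false2 <- sqrt(dNN^2 + extra^2) / sigma > aTol
  mean(false1 | false2)
}

#' Choose embedding dimension and lag for a channel
#'
#' Standard heuristics from the state-space-reconstruction literature:
#' the lag is the first local minimum of the lagged mutual information
#' (falling back to the first zero crossing of the autocorrelation when no
#' minimum exists within `maxLag`), and the dimension is the smallest D whose
#' false-nearest-neighbor fraction drops below `fnnThreshold` (capped at
#' `maxDim`, with a warning when the criterion never stabilizes, as for pure
#' noise). Both choices can be overridden per variable via `dim`/`lag`.
#'
#' @param series a [TimeSeries-class] or numeric vector.
#' @param maxDim largest dimension considered (default 8).
#' @param maxLag largest lag considered (default 40 samples).
#' @param channel channel index or name.
#' @param dim,lag optional user overrides, returned verbatim when given.
#' @param fnnThreshold acceptable false-nearest-neighbor fraction.
#' @return An [EmbeddingParams-class].
#' @export
selectEmbeddingParams <- function(series, maxDim = 8L, maxLag = 40L,
                                  channel = 1L, dim = NULL, lag = NULL,
                                  fnnThreshold = 0.05) {
  if (!is.null(dim) && !is.null(lag)) return(EmbeddingParams(dim, lag))
  x <- if (is(series, "TimeSeries")) tsChannel(series, channel)
       else as.numeric(series)
  if (sd(x) == 0)
    stop("cannot select embedding parameters for a constant series",
         call. = FALSE)
  maxLag <- min(maxLag, length(x) %/% 3L)
  if (is.null(lag)) {
    mi <- vapply(seq_len(maxLag), function(l) laggedMutualInformation(x, l),
                 numeric(1))
    # first local minimum, but only when it is a genuine dip: the curve must
    # rise again by a margin relative to its overall range, otherwise a flat
    # stretch of estimator noise (as for strongly periodic signals) would be
    # mistaken for structure
    lagSel <- NA_integer_
    margin <- 0.05 * diff(range(mi))
    if (maxLag >= 3L) {
      for (l in 2:(maxLag - 1L)) {
        if (mi[l] < mi[l - 1L] && mi[l] <= mi[l + 1L]) {
          horizon <- mi[(l + 1L):min(maxLag, l + 5L)]
          if (any(horizon > mi[l] + margin)) { lagSel <- l; break }
        }
      }
    }
    if (is.na(lagSel)) {
      # fallback: first zero crossing of the autocorrelation
      ac <- acf(x, lag.max = maxLag, plot = FALSE)$acf[-1L]
      z <- which(ac <= 0)
      lagSel <- if (length(z)) z[1L] else maxLag
    }
    lag <- lagSel
  }
  if (is.null(dim)) {
    dimSel <- NA_integer_
    for (D in seq_len(maxDim)) {
      f <- falseNeighborFraction(x, D, lag)
      if (!is.na(f) && f < fnnThreshold) { dimSel <- D; break }
    }
    if (is.na(dimSel)) {
      warning("false-nearest-neighbor fraction never fell below ",
              fnnThreshold, "; using maxDim = ", maxDim)
      dimSel <- maxDim
    }
    dim <- dimSel
  }
  EmbeddingParams(dim, lag)
}
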
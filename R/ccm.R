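#' Cross-map estimate of one value from the other variable's manifold
#'
#' The nearest-neighbor cross map at time t: the k nearest neighbors of the
#' delay vector at t are located in `mx` (excluding points within
#' `exclusionWindow` samples of t), and the contemporaneous values of the
#' other variable at those neighbor times are averaged with exponential
#' weights `w_i = exp(-d_i / d_1)` (d_1 = distance to the nearest neighbor),
#' normalized to sum to 1. When `d_1 = 0` the weight collapses uniformly
#' onto the exact matches.
#'
#' @param mx a [DelayEmbedding-class] of the predicting variable.
#' @param yValues values of the variable being estimated, indexed like
#'   `embeddingTimes(mx)` (one value per embedding point).
#' @param t index (into the embedding points) of the target time.
#' @param k number of neighbors; the convention is D + 1 where D is the
#'   embedding dimension.
#' @param exclusionWindow Theiler window in samples around t.
#' @return The weighted-average estimate of `yValues[t]`.
#' @export
crossMapEstimate <- function(mx, yValues, t, k = embeddingDim(mx) + 1L,
                             exclusionWindow = 0L) {
  pts <- embeddingPoints(mx)
  times <- embeddingTimes(mx)
  if (length(yValues) != nrow(pts))
    stop("need one y value per embedding point")
  admissible <- which(abs(times - times[t]) > exclusionWindow)
  if (length(admissible) < k)
    stop(sprintf("only %d admissible neighbors, need %d",
                 length(admissible), k), call. = FALSE)
  d <- sqrt(colSums((t(pts[admissible, , drop = FALSE]) - pts[t, ])^2))
  nn <- admissible[order(d)[seq_len(k)]]
  dnn <- sort(d)[seq_len(k)]
  if (dnn[1L] == 0) {
    w <- as.numeric(dnn == 0)
  } else {
    w <- exp(-dnn / dnn[1L])
  }
  w <- w / sum(w)
  sum(w * yValues[nn])
}

#' Convergent cross mapping score between two series
#'
#' The CCM baseline: every admissible point of the driven variable's
#' reconstruction cross-maps an estimate of the candidate driver, and the
#' score is the Pearson correlation between estimates and true values.
#' Direction convention (pinned once, used everywhere): estimating y from
#' M_X gives CCM(y -> x), because M_X can only reconstruct y if y drives x.
#' Hence the reported score(x -> y) is obtained by cross-mapping x from the
#' manifold of the driven variable y. Each delay vector estimates the
#' driver's value at its most recent coordinate time, so the estimate uses
#' only the driven variable's present and past (the standard backward-lag
#' shadow-manifold convention).
#'
#' @inheritParams ccs
#' @param k number of nearest neighbors (default D + 1).
#' @return A [CouplingScore-class], or a list of two when
#'   `direction = "both"`. Scores are clipped to `[-1, 1]`; a zero-variance
#'   estimate yields score 0 with a warning.
#' @export
ccm <- function(x, y = NULL, params = NULL,
                direction = c("both", "x_to_y", "y_to_x"),
                exclusionWindow = NULL, k = NULL, normalize = TRUE,
                labels = c("x", "y")) {
  direction <- match.arg(direction)
  ch <- resolvePair(x, y, labels)
  if (is.null(params)) params <- selectEmbeddingParams(ch$x)
  if (is.null(exclusionWindow))
    exclusionWindow <- embeddingDim(params) * embeddingLag(params)
  if (is.null(k)) k <- embeddingDim(params) + 1L
  xv <- if (normalize) zScore(ch$x) else ch$x
  yv <- if (normalize) zScore(ch$y) else ch$y
  span <- (embeddingDim(params) - 1L) * embeddingLag(params)
  oneDirection <- function(dir) {
    # score(src -> tgt): cross-map src values from the driven manifold M_tgt
    if (dir == "x_to_y") {
      lib <- delayEmbed(yv, params); est <- xv
      src <- ch$labels[1L]; tgt <- ch$labels[2L]
    } else {
      lib <- delayEmbed(xv, params); est <- yv
      src <- ch$labels[2L]; tgt <- ch$labels[1L]
    }
    # contemporaneous alignment at the last coordinate time: each delay
    # vector predicts the driver's value at its most recent sample
    estAligned <- est[embeddingTimes(lib) + span]
    pred <- crossMapAll(lib, estAligned, k, exclusionWindow)
    value <- if (sd(pred) == 0 || sd(estAligned) == 0) {
      warning("zero-variance cross-map estimates; score defined as 0")
      0
    } else cor(pred, estAligned)
    CouplingScore(src, tgt, "CCM", max(-1, min(1, value)))
  }
  if (direction == "both")
    list(x_to_y = oneDirection("x_to_y"), y_to_x = oneDirection("y_to_x"))
  else oneDirection(direction)
}

# Vectorized cross map over all admissible target times: one distance-matrix
# pass instead of calling crossMapEstimate() per point.
crossMapAll <- function(lib, values, k, exclusionWindow) {
  pts <- embeddingPoints(lib)
  times <- embeddingTimes(lib)
  n <- nrow(pts)
  dm <- as.matrix(dist(pts))
  dm[abs(outer(times, times, "-")) <= exclusionWindow] <- Inf
  vapply(seq_len(n), function(t) {
    d <- dm[t, ]
    ord <- order(d)[seq_len(k)]
    dnn <- d[ord]
    if (!is.finite(dnn[k]))
      stop(sprintf("only %d admissible neighbors, need %d",
                   sum(is.finite(d)), k), call. = FALSE)
    w <- if (dnn[1L] == 0) as.numeric(dnn == 0) else exp(-dnn / dnn[1L])
    w <- w / sum(w)
    sum(w * values[ord])
  }, numeric(1))
}
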
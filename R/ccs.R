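#' Paired distance ranks between two delay embeddings
#'
#' The rank-correspondence statistic starts here: for every unordered pair of
#' retained time points (i, j) with `|i - j| > exclusionWindow` (a
#' Theiler-style window that keeps trivially close temporal neighbors from
#' dominating the low ranks), the Euclidean distances between the two delay
#' vectors are computed in each manifold and converted to ranks (ascending,
#' ties averaged). Both embeddings are restricted to the intersection of
#' their valid time indices so that entry k of the two rank vectors always
#' refers to the same pair of time points.
#'
#' When the number of admissible pairs exceeds `maxPairs` the pairs are
#' uniformly subsampled with a seeded RNG; this is an approximation for
#' tractability on long series.
#'
#' @param mx,my [DelayEmbedding-class] objects from the two variables.
#' @param exclusionWindow minimum temporal separation of retained pairs
#'   (samples); pairs with `|i - j| <= exclusionWindow` are dropped.
#' @param maxPairs pair budget before uniform subsampling (default 2e6).
#' @param seed seed for the subsampling RNG.
#' @return A [RankCorrespondence-class].
#' @export
pairwiseRankDistances <- function(mx, my, exclusionWindow = 0L,
                                  maxPairs = 2e6, seed = NULL) {
  if (exclusionWindow < 0L) stop("exclusionWindow must be >= 0")
  common <- intersect(embeddingTimes(mx), embeddingTimes(my))
  px <- embeddingPoints(mx)[match(common, embeddingTimes(mx)), , drop = FALSE]
  py <- embeddingPoints(my)[match(common, embeddingTimes(my)), , drop = FALSE]
  n <- length(common)
  if (n < 2L) stop("fewer than 2 retained time points", call. = FALSE)
  pr <- pairIndexUpper(n)
  keep <- abs(common[pr[, 1L]] - common[pr[, 2L]]) > exclusionWindow
  pr <- pr[keep, , drop = FALSE]
  if (nrow(pr) < 2L)
    stop("fewer than 2 retained pairs after the temporal-exclusion rule",
         call. = FALSE)
  dxAll <- as.numeric(dist(px))[keep]
  dyAll <- as.numeric(dist(py))[keep]
  if (nrow(pr) > maxPairs) {
    sub <- withSeed(seed, sort(sample.int(nrow(pr), maxPairs)))
    pr <- pr[sub, , drop = FALSE]
    dxAll <- dxAll[sub]
    dyAll <- dyAll[sub]
  }
  if (all(dxAll == 0) || all(dyAll == 0))
    stop("degenerate input: all pairwise distances are zero in one manifold",
         call. = FALSE)
  new("RankCorrespondence",
      rankX = rank(dxAll, ties.method = "average"),
      rankY = rank(dyAll, ties.method = "average"),
      nPairs = nrow(pr),
      pairIndex = cbind(common[pr[, 1L]], common[pr[, 2L]]))
}

# Upper-triangle index pairs (i < j) in the column-major order used by dist().
pairIndexUpper <- function(n) {
  j <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  i <- sequence((n - 1L):1L) + j
  cbind(j, i, deparse.level = 0L)
}

#' Signed rank errors in conditioning-rank order
#'
#' The per-pair rank error is `ERR = R_X - R_Y`. Direction matters only
#' through the ordering: for the influence of x on y the errors are ordered
#' by the ranks in the manifold of the driven variable y (`R_Y`), because a
#' driven variable inherits information about its driver, so low ranks in
#' M_Y should predict low ranks in M_X; for y on x they are ordered by
#' `R_X`.
#'
#' @param rc a [RankCorrespondence-class]; `rankX`/`rankY` come from the
#'   manifolds of x and y respectively.
#' @param direction `"x_to_y"` (order by `R_Y`) or `"y_to_x"` (order by
#'   `R_X`).
#' @return Numeric vector of signed errors `R_X - R_Y`, ordered by the
#'   conditioning rank (lowest first).
#' @export
rankError <- function(rc, direction = c("x_to_y", "y_to_x")) {
  direction <- match.arg(direction)
  err <- rc@rankX - rc@rankY
  cond <- if (direction == "x_to_y") rc@rankY else rc@rankX
  err[order(cond)]
}

#' Expected squared rank error under uncorrelated ranks
#'
#' For two independent uniform random rankings of n pairs the marginal
#' expectation of `(R_X - R_Y)^2` is `(n^2 - 1)/6`. Conditioning on one rank
#' being r gives `(n^2 - 1)/12 + ((n + 1)/2 - r)^2`. The conditional form
#' is the default normalizer for the error curve: the chance level
#' genuinely varies with the conditioning rank (an extreme conditioning
#' rank can err further than a central one), and since the score
#' extrapolates the curve at low conditioning ranks, normalizing there
#' against the flat marginal value would push uncorrelated series toward
#' -1 instead of 0.
#'
#' @param nPairs number of ranked pairs (>= 2).
#' @param mode `"marginal"` or `"conditional"`.
#' @param rank conditioning rank(s) r, required for `mode = "conditional"`;
#'   may be a vector.
#' @return The null expectation (scalar, or vector along `rank`).
#' @export
nullErr2 <- function(nPairs, mode = c("marginal", "conditional"),
                     rank = NULL) {
  mode <- match.arg(mode)
  n <- as.numeric(nPairs)
  if (n < 2) stop("need at least 2 pairs")
  if (mode == "marginal") return((n^2 - 1) / 6)
  if (is.null(rank)) stop("conditional mode requires the conditioning rank")
  (n^2 - 1) / 12 + ((n + 1) / 2 - rank)^2
}

#' Cumulative normalized rank-error curve
#'
#' Each squared error is normalized against the null expectation,
#' `NERR2 = (null - ERR^2)/null` (1 = perfect correspondence, 0 = chance),
#' and the curve value at normalized rank k/n is the mean NERR2 over the k
#' lowest conditioning ranks. Restricting attention to low ranks focuses the
#' comparison on the most densely covered portion of the manifold, where the
#' reconstruction is most informative.
#'
#' @param err signed rank errors in conditioning-rank order (from
#'   [rankError()]).
#' @param null the null expectation: a scalar (marginal) or a vector aligned
#'   with `err` (conditional, one value per conditioning rank).
#' @return An [ErrorCurve-class] with `rankGrid = (1:n)/n`.
#' @export
nerr2Curve <- function(err, null) {
  n <- length(err)
  if (n == 0L) stop("empty error vector")
  if (any(null <= 0)) stop("null expectation must be positive")
  if (!length(null) %in% c(1L, n))
    stop("null must be scalar or match the error vector length")
  nerr2 <- (null - err^2) / null
  new("ErrorCurve", rankGrid = seq_len(n) / n,
      cumNerr2 = cumsum(nerr2) / seq_len(n),
      nullValue = if (length(null) == 1L) null else mean(null))
}

#' Coupling score from an error curve
#'
#' The curve is thresholded at `maxRankFrac` and fit by least squares to
#' `f(r) = a * exp(-b * r) + c` with `b >= 0`; the score is the y-intercept
#' `f(0) = a + c`, clipped to `[-1, 1]`. Extrapolating to rank zero from the
#' best-fit curve estimates the local rank correspondence while borrowing
#' strength from larger scales, where the cumulative average is far less
#' variable than the raw low-rank errors. If the nonlinear fit fails to
#' converge, the intercept of a linear fit on the lowest decile of the
#' thresholded curve is used instead and `fitOk` is set to `FALSE`.
#'
#' @param curve an [ErrorCurve-class].
#' @param maxRankFrac threshold on the normalized rank, in (0, 1]
#'   (default 0.25).
#' @return A list with elements `value` (the score) and `fitOk`.
#' @export
ccsScoreFromCurve <- function(curve, maxRankFrac = 0.25) {
  if (maxRankFrac <= 0 || maxRankFrac > 1)
    stop("maxRankFrac must lie in (0, 1]")
  keep <- curve@rankGrid <= maxRankFrac
  if (sum(keep) < 3L)
    stop(sprintf(
      "fewer than 3 curve points at or below maxRankFrac = %g", maxRankFrac),
      call. = FALSE)
  r <- curve@rankGrid[keep]
  y <- curve@cumNerr2[keep]
  fitOk <- TRUE
  value <- tryCatch({
    c0 <- mean(tail(y, max(3L, length(y) %/% 4L)))
    a0 <- y[1L] - c0
    fit <- minpack.lm::nlsLM(
      y ~ a * exp(-b * r) + c,
      start = list(a = a0, b = 1, c = c0),
      lower = c(a = -Inf, b = 0, c = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    unname(cf["a"] + cf["c"])
  }, error = function(e) {
    fitOk <<- FALSE
    nLow <- max(2L, ceiling(length(r) / 10))
    cf <- coef(lm(y[seq_len(nLow)] ~ r[seq_len(nLow)]))
    unname(cf[1L])
  })
  list(value = max(-1, min(1, value)), fitOk = fitOk)
}

#' Convergent Cross Sorting score between two series
#'
#' The full CCS pipeline: (optionally z-score, then) delay-embed each
#' variable, rank all admissible pairwise distances in each reconstruction,
#' form the signed rank errors in conditioning-rank order, normalize against
#' the uncorrelated-rank null, and extrapolate the cumulative normalized
#' error curve to rank zero. A score near 1 means the low-rank distance
#' structure of the driven variable's manifold predicts that of the driver's
#' manifold — evidence that the two variables belong to one dynamical
#' system, with the stated direction of influence.
#'
#' @param x,y [TimeSeries-class] objects or numeric vectors of equal length
#'   (a multichannel `x` with `y` missing is also accepted when it has
#'   exactly 2 channels).
#' @param params shared [EmbeddingParams-class]; when `NULL`, selected from
#'   `x` via [selectEmbeddingParams()] and shared by both variables so that
#'   scores stay commensurable.
#' @param direction `"both"` (default), `"x_to_y"`, or `"y_to_x"`.
#' @param exclusionWindow Theiler window in samples; default `dim * lag`.
#' @param maxRankFrac threshold for the curve fit (default 0.25).
#' @param nullMode `"conditional"` (default, rank-dependent chance level)
#'   or `"marginal"` null normalization.
#' @param normalize z-score each series before embedding (default TRUE).
#' @param maxPairs pair budget before seeded subsampling.
#' @param seed seed for pair subsampling.
#' @param labels length-2 character vector naming x and y.
#' @return A [CouplingScore-class], or a list of two (`x_to_y`, `y_to_x`)
#'   when `direction = "both"`.
#' @examples
#' x <- simulateLogisticMap(
#'   makeTopologies("two_var", K = c(0.3, 0))[[1]], L = 300,
#'   noise = NoiseSpec(seed = 7))
#' s <- ccs(trialSeries(x), params = EmbeddingParams(2, 1))
#' s$x_to_y
#' @export
ccs <- function(x, y = NULL, params = NULL,
                direction = c("both", "x_to_y", "y_to_x"),
                exclusionWindow = NULL, maxRankFrac = 0.25,
                nullMode = c("conditional", "marginal"), normalize = TRUE,
                maxPairs = 2e6, seed = NULL, labels = c("x", "y")) {
  direction <- match.arg(direction)
  nullMode <- match.arg(nullMode)
  ch <- resolvePair(x, y, labels)
  if (is.null(params)) params <- selectEmbeddingParams(ch$x)
  if (is.null(exclusionWindow))
    exclusionWindow <- embeddingDim(params) * embeddingLag(params)
  xv <- if (normalize) zScore(ch$x) else ch$x
  yv <- if (normalize) zScore(ch$y) else ch$y
  rc <- pairwiseRankDistances(delayEmbed(xv, params), delayEmbed(yv, params),
                              exclusionWindow = exclusionWindow,
                              maxPairs = maxPairs, seed = seed)
  oneDirection <- function(dir) {
    err <- rankError(rc, dir)
    null <- if (nullMode == "marginal") nullErr2(rc@nPairs) else
      nullErr2(rc@nPairs, "conditional", rank = sort(
        if (dir == "x_to_y") rc@rankY else rc@rankX))
    fit <- ccsScoreFromCurve(nerr2Curve(err, null), maxRankFrac)
    src <- if (dir == "x_to_y") ch$labels[1L] else ch$labels[2L]
    tgt <- if (dir == "x_to_y") ch$labels[2L] else ch$labels[1L]
    CouplingScore(src, tgt, "CCS", fit$value, fitOk = fit$fitOk)
  }
  if (direction == "both")
    list(x_to_y = oneDirection("x_to_y"), y_to_x = oneDirection("y_to_x"))
  else oneDirection(direction)
}

# Resolve the (x, y) argument forms shared by ccs()/ccm().
resolvePair <- function(x, y, labels) {
  if (is.null(y)) {
    if (!is(x, "TimeSeries") || nChannels(x) != 2L)
      stop("when y is missing, x must be a 2-channel TimeSeries")
    labels <- channelNames(x)
    return(list(x = tsChannel(x, 1L), y = tsChannel(x, 2L), labels = labels))
  }
  xv <- if (is(x, "TimeSeries")) tsChannel(x, 1L) else as.numeric(x)
  yv <- if (is(y, "TimeSeries")) tsChannel(y, 1L) else as.numeric(y)
  if (length(xv) != length(yv)) stop("series must have equal length")
  list(x = xv, y = yv, labels = labels)
}

#' Surrogate significance of a CCS score
#'
#' One-sided surrogate test: the second series is circularly shifted by a
#' random offset larger than the exclusion window (and smaller than
#' `L - exclusionWindow`), destroying the temporal alignment while
#' preserving each series' own dynamics, and the score is recomputed for
#' each surrogate. The p-value uses the plus-one estimator
#' `p = (1 + #(surrogate >= observed)) / (1 + nSurrogates)`, so it is never
#' exactly zero.
#'
#' @inheritParams ccs
#' @param nSurrogates number of circular-shift surrogates (>= 19).
#' @param seed RNG seed; makes the surrogate set reproducible.
#' @param direction which directed score to test.
#' @return The observed [CouplingScore-class] with its `pValue` slot filled.
#' @export
ccsSignificance <- function(x, y = NULL, params = NULL, nSurrogates = 99L,
                            seed = 1L, direction = c("x_to_y", "y_to_x"),
                            exclusionWindow = NULL, ...) {
  direction <- match.arg(direction)
  if (nSurrogates < 19L) stop("need at least 19 surrogates")
  ch <- resolvePair(x, y, c("x", "y"))
  if (is.null(params)) params <- selectEmbeddingParams(ch$x)
  if (is.null(exclusionWindow))
    exclusionWindow <- embeddingDim(params) * embeddingLag(params)
  L <- length(ch$x)
  if (L < 3L * exclusionWindow)
    stop("series shorter than 3x the exclusion window", call. = FALSE)
  obs <- ccs(ch$x, ch$y, params = params, direction = direction,
             exclusionWindow = exclusionWindow, labels = ch$labels, ...)
  shifts <- withSeed(seed, sample(
    seq(exclusionWindow + 1L, L - exclusionWindow - 1L), nSurrogates,
    replace = TRUE))
  surr <- vapply(shifts, function(s) {
    ys <- c(ch$y[(s + 1L):L], ch$y[1L:s])
    scoreValue(ccs(ch$x, ys, params = params, direction = direction,
                   exclusionWindow = exclusionWindow, ...))
  }, numeric(1))
  p <- (1 + sum(surr >= scoreValue(obs))) / (1 + nSurrogates)
  initialize(obs, pValue = p)
}
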
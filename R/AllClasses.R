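#' @import methods
#' @importFrom stats acf approx coef cor cor.test dist fft kmeans lm median
#'   na.omit nls p.adjust pbinom prcomp predict quantile rnorm runif sd
#'   t.test var wilcox.test
#' @importFrom utils head read.csv write.csv tail
NULL

#' Uniformly sampled multichannel time series
#'
#' The basic data container: a samples-by-channels matrix of observations
#' taken at a fixed sampling interval. All downstream machinery (delay
#' embedding, coupling scores, simulators) consumes and produces this class.
#'
#' @slot values numeric matrix, one row per sample, one column per channel.
#' @slot dt sampling interval in arbitrary time units (default 1).
#' @slot labels character vector of channel names (column names of `values`).
#'
#' @aliases TimeSeries-class
#' @export
setClass("TimeSeries",
  representation(values = "matrix", dt = "numeric", labels = "character"))

setValidity("TimeSeries", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (nrow(v) < 2L) return("a time series needs at least 2 samples")
  if (!all(is.finite(v))) return("values must be finite (no NA/NaN/Inf)")
  if (length(object@dt) != 1L || object@dt <= 0)
    return("dt must be a single positive number")
  if (length(object@labels) != ncol(v))
    return("labels must name every channel")
  TRUE
})

#' Construct a TimeSeries
#'
#' @param values numeric vector (one channel) or samples-by-channels matrix.
#' @param dt sampling interval (arbitrary units).
#' @param labels optional channel names; defaults to column names or
#'   `"V1", "V2", ...`.
#' @return A [TimeSeries-class] object.
#' @examples
#' ts <- TimeSeries(cbind(x = sin(1:100 / 5), y = cos(1:100 / 5)))
#' nSamples(ts)
#' channelNames(ts)
#' @export
TimeSeries <- function(values, dt = 1, labels = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(labels)) {
    labels <- colnames(values)
    if (is.null(labels)) labels <- paste0("V", seq_len(ncol(values)))
  }
  colnames(values) <- labels
  new("TimeSeries", values = values, dt = as.numeric(dt),
      labels = as.character(labels))
}

#' Delay-embedding parameters
#'
#' @slot embDim embedding dimension D (number of delayed copies).
#' @slot embLag delay tau, in samples, between consecutive coordinates.
#' @aliases EmbeddingParams-class
#' @export
setClass("EmbeddingParams",
  representation(embDim = "integer", embLag = "integer"))

setValidity("EmbeddingParams", function(object) {
  if (length(object@embDim) != 1L || object@embDim < 1L)
    return("embedding dimension must be a positive integer")
  if (length(object@embLag) != 1L || object@embLag < 1L)
    return("embedding lag must be a positive integer")
  TRUE
})

#' Construct embedding parameters
#'
#' @param dim embedding dimension D (positive integer).
#' @param lag delay tau in samples (positive integer).
#' @return An [EmbeddingParams-class] object.
#' @export
EmbeddingParams <- function(dim, lag) {
  new("EmbeddingParams", embDim = as.integer(dim), embLag = as.integer(lag))
}

#' Delay-coordinate reconstruction of an attractor
#'
#' A matrix of delay vectors built from one scalar channel: row i is
#' `c(x[i], x[i + tau], ..., x[i + (D-1) tau])`. The point cloud is the
#' reconstructed manifold used by both the rank-correspondence (CCS) and
#' nearest-neighbor cross-mapping (CCM) statistics.
#'
#' @slot points numeric matrix, n_points x D.
#' @slot times integer vector, the index of the first coordinate of each row.
#' @slot params the [EmbeddingParams-class] used.
#' @aliases DelayEmbedding-class
#' @export
setClass("DelayEmbedding",
  representation(points = "matrix", times = "integer",
                 params = "EmbeddingParams"))

setValidity("DelayEmbedding", function(object) {
  if (nrow(object@points) != length(object@times))
    return("one time index per delay vector required")
  if (ncol(object@points) != object@params@embDim)
    return("point dimension must equal the embedding dimension")
  TRUE
})

#' Paired distance ranks between two reconstructions
#'
#' For every retained time-point pair (i, j) the Euclidean distances in the
#' two manifolds are converted to ranks (ascending, ties averaged). The same
#' pair ordering underlies both rank vectors, so element k of `rankX` and
#' `rankY` describes the same pair of time points.
#'
#' @slot rankX distance ranks in the first manifold.
#' @slot rankY distance ranks in the second manifold (same pair order).
#' @slot nPairs number of retained pairs.
#' @slot pairIndex integer matrix (nPairs x 2) of the time-point pairs.
#' @aliases RankCorrespondence-class
#' @export
setClass("RankCorrespondence",
  representation(rankX = "numeric", rankY = "numeric", nPairs = "integer",
                 pairIndex = "matrix"))

setValidity("RankCorrespondence", function(object) {
  if (length(object@rankX) != length(object@rankY))
    return("rank vectors must have equal length")
  if (length(object@rankX) != object@nPairs)
    return("nPairs must equal the rank vector length")
  TRUE
})

#' Cumulative normalized rank-error curve
#'
#' Per-pair squared rank errors are normalized against the null expectation
#' for uncorrelated ranks, `NERR2 = (null - ERR^2)/null`, and averaged
#' cumulatively from the lowest conditioning rank upward. A value of 1 means
#' perfect rank correspondence, 0 chance level.
#'
#' @slot rankGrid conditioning ranks normalized to (0, 1].
#' @slot cumNerr2 cumulative mean of NERR2 up to each grid point.
#' @slot nullValue expected squared rank error under uncorrelated ranks.
#' @aliases ErrorCurve-class
#' @export
setClass("ErrorCurve",
  representation(rankGrid = "numeric", cumNerr2 = "numeric",
                 nullValue = "numeric"))

setValidity("ErrorCurve", function(object) {
  if (length(object@rankGrid) != length(object@cumNerr2))
    return("rankGrid and cumNerr2 must have equal length")
  if (is.unsorted(object@rankGrid)) return("rankGrid must be monotone")
  if (any(object@nullValue <= 0)) return("null expectation must be positive")
  TRUE
})

#' A directed coupling score
#'
#' Direction convention: `value` for source x and target y quantifies the
#' influence of x on y, score(x -> y). For both methods this is estimated
#' from the reconstruction of the driven variable y, which inherits
#' information about its driver.
#'
#' @slot source name of the candidate driving variable.
#' @slot target name of the candidate driven variable.
#' @slot method "CCS" or "CCM".
#' @slot value the score, clipped to `[-1, 1]`.
#' @slot fitOk FALSE when the exponential curve fit fell back to a linear fit.
#' @slot pValue surrogate-test p-value, or NA when not computed.
#' @aliases CouplingScore-class
#' @export
setClass("CouplingScore",
  representation(source = "character", target = "character",
                 method = "character", value = "numeric", fitOk = "logical",
                 pValue = "numeric"))

setValidity("CouplingScore", function(object) {
  if (!object@method %in% c("CCS", "CCM"))
    return("method must be 'CCS' or 'CCM'")
  if (!is.finite(object@value)) return("score value must be finite")
  TRUE
})

CouplingScore <- function(source, target, method, value, fitOk = TRUE,
                          pValue = NA_real_) {
  new("CouplingScore", source = source, target = target, method = method,
      value = value, fitOk = fitOk, pValue = as.numeric(pValue))
}

#' Generating network: topology, coupling strengths, system type
#'
#' @slot nVars number of variables.
#' @slot coupling matrix K where `K[j, i]` is the strength of the edge
#'   j -> i (zero diagonal).
#' @slot system "LM" (logistic maps), "VDP" (Van der Pol), or "AR".
#' @slot systemParams list of per-variable intrinsic parameters.
#' @slot topologyTag name of the topology template.
#' @aliases NetworkSpec-class
#' @export
setClass("NetworkSpec",
  representation(nVars = "integer", coupling = "matrix", system = "character",
                 systemParams = "list", topologyTag = "character"))

setValidity("NetworkSpec", function(object) {
  K <- object@coupling
  if (nrow(K) != object@nVars || ncol(K) != object@nVars)
    return("coupling matrix must be nVars x nVars")
  if (any(diag(K) != 0)) return("coupling matrix must have a zero diagonal")
  if (any(K < 0)) return("coupling strengths must be nonnegative")
  if (!object@system %in% c("LM", "VDP", "AR"))
    return("system must be one of LM, VDP, AR")
  TRUE
})

#' Construct a NetworkSpec
#' @param coupling square matrix K, `K[j, i]` = strength of edge j -> i.
#' @param system "LM", "VDP" or "AR".
#' @param systemParams list of per-variable intrinsic parameters (see the
#'   simulator for each system).
#' @param topologyTag free-form template name.
#' @return A [NetworkSpec-class].
#' @export
NetworkSpec <- function(coupling, system, systemParams = list(),
                        topologyTag = "custom") {
  coupling <- as.matrix(coupling)
  new("NetworkSpec", nVars = nrow(coupling), coupling = coupling,
      system = system, systemParams = systemParams, topologyTag = topologyTag)
}

#' Noise settings for a simulated trial
#'
#' @slot snrDb measurement signal-to-noise ratio in dB (`Inf` = no noise).
#' @slot dynEps dynamical (process) noise magnitude injected into the state.
#' @slot seed RNG seed for the trial.
#' @aliases NoiseSpec-class
#' @export
setClass("NoiseSpec",
  representation(snrDb = "numeric", dynEps = "numeric", seed = "integer"))

setValidity("NoiseSpec", function(object) {
  if (!(object@snrDb >= 0)) return("snrDb must be nonnegative (Inf allowed)")
  if (object@dynEps < 0) return("dynEps must be nonnegative")
  TRUE
})

#' @param snrDb measurement SNR in dB; `Inf` for noise-free observation.
#' @param dynEps dynamical noise magnitude (0 = deterministic dynamics).
#' @param seed integer RNG seed.
#' @rdname NoiseSpec-class
#' @export
NoiseSpec <- function(snrDb = Inf, dynEps = 0, seed = 1L) {
  new("NoiseSpec", snrDb = as.numeric(snrDb), dynEps = as.numeric(dynEps),
      seed = as.integer(seed))
}

#' One simulated trial: series, generating spec, and ground truth
#'
#' @slot series the observed [TimeSeries-class] (after burn-in and noise).
#' @slot spec the generating [NetworkSpec-class].
#' @slot noise the [NoiseSpec-class] applied.
#' @slot truth logical matrix, `truth[j, i]` TRUE when edge j -> i exists.
#' @aliases TrialResult-class
#' @export
setClass("TrialResult",
  representation(series = "TimeSeries", spec = "NetworkSpec",
                 noise = "NoiseSpec", truth = "matrix"))

setValidity("TrialResult", function(object) {
  if (!identical(dim(object@truth), dim(object@spec@coupling)))
    return("truth must match the coupling matrix shape")
  if (!identical(unname(object@truth), unname(object@spec@coupling > 0)))
    return("truth must equal coupling > 0")
  TRUE
})

#' Windowed directed coupling scores for a 3-channel recording
#'
#' For n channels there are n(n-1) ordered pairs; with the 3 channels used
#' throughout, every window is summarized by a 6-dimensional directed score
#' vector.
#'
#' @slot scores numeric array, epochs x windows x directed pairs.
#' @slot windowLen window length in samples.
#' @slot stepLen window step in samples.
#' @slot epochLabels condition tag per epoch.
#' @slot pairNames `"src->tgt"` name per score dimension.
#' @aliases WindowedScores-class
#' @export
setClass("WindowedScores",
  representation(scores = "array", windowLen = "integer", stepLen = "integer",
                 epochLabels = "character", pairNames = "character"))

setValidity("WindowedScores", function(object) {
  d <- dim(object@scores)
  if (length(d) != 3L) return("scores must be a 3-d array")
  if (d[3] != length(object@pairNames))
    return("one name per directed-pair dimension required")
  if (d[1] != length(object@epochLabels))
    return("one condition label per epoch required")
  if (!all(is.finite(object@scores))) return("scores must be finite")
  TRUE
})

#' Per-epoch network-state label sequences
#'
#' @slot labels integer matrix, epochs x windows, states in 1..k.
#' @slot k number of states.
#' @slot epochLabels condition tag per epoch.
#' @aliases StateSequences-class
#' @export
setClass("StateSequences",
  representation(labels = "matrix", k = "integer", epochLabels = "character"))

setValidity("StateSequences", function(object) {
  if (any(object@labels < 1L | object@labels > object@k))
    return("state labels must lie in 1..k")
  if (nrow(object@labels) != length(object@epochLabels))
    return("one condition label per epoch required")
  TRUE
})
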
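#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' The area under the ROC curve equals the probability that a randomly
#' chosen positive scores higher than a randomly chosen negative (ties
#' counted half), computed here directly from the rank-sum statistic.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) ground-truth labels, TRUE = coupled.
#' @return The AUC in `[0, 1]`.
#' @examples
#' rocAuc(c(0.9, 0.7, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE))
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("cannot form an ROC: need both coupled and non-coupled labels",
         call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# Percentile bootstrap CI for a pooled AUC, stratified by label.
aucBootstrapCI <- function(scores, labels, nBoot = 1000L, level = 0.95,
                           seed = NULL) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  stat <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    rocAuc(c(sample(pos, replace = TRUE), sample(neg, replace = TRUE)),
           rep(c(TRUE, FALSE), c(length(pos), length(neg))))
  }, numeric(1)))
  alpha <- (1 - level) / 2
  unname(quantile(stat, c(alpha, 1 - alpha)))
}

#' Detection-accuracy experiment: pooled ROC AUC per condition
#'
#' For each condition in the crossed grid of `L`, `snrDb`, and `dynEps`,
#' simulates `nTrials` three-variable networks on transitive-free
#' topologies (cycled across trials, both edges of a trial sharing one
#' coupling strength drawn from `KRange`), scores all six directed channel
#' pairs of every trial with each method, pools the scores labeled by the
#' ground-truth edges, and computes the pooled Mann-Whitney ROC AUC with a
#' stratified percentile-bootstrap confidence interval.
#'
#' @param system `"LM"`, `"VDP"`, or `"AR"`.
#' @param L vector of series lengths to cross.
#' @param nTrials trials per condition (default 200).
#' @param snrDb vector of measurement SNRs in dB (default Inf).
#' @param dynEps vector of dynamical-noise magnitudes (default 0; for
#'   `"AR"` the innovations scale, default 1).
#' @param KRange range from which each trial's shared edge strength is
#'   drawn uniformly; a single number fixes K.
#' @param methods methods to evaluate.
#' @param params shared [EmbeddingParams-class] for scoring (defaults per
#'   system: D = 2, lag = 1 for the maps; D = 3, lag = 5 for the
#'   oscillators; D = 3, lag = 1 for AR).
#' @param seed master seed; every trial derives its own child seed.
#' @param nBoot bootstrap resamples for the CI (default 1000).
#' @param templates topology templates cycled over trials.
#' @param ranges intrinsic-parameter range overrides, see
#'   [randomizeSystemParams()].
#' @param keepScores attach the pooled per-pair score table as
#'   `attr(result, "scores")` (for bootstrap method comparisons).
#' @param ... passed to the system simulator.
#' @return A data.frame: one row per condition x method with `auc`,
#'   `ci_low`, `ci_high`, `n_scores`.
#' @export
runDetection <- function(system = c("LM", "VDP", "AR"), L = 400L,
                         nTrials = 200L, snrDb = Inf, dynEps = NULL,
                         KRange = NULL, methods = c("CCS", "CCM"),
                         params = NULL, seed = 1L, nBoot = 1000L,
                         templates = c("common_driver", "common_sink",
                                       "bidirectional_pair"),
                         ranges = list(), keepScores = FALSE, ...) {
  system <- match.arg(system)
  if (is.null(dynEps)) dynEps <- if (system == "AR") 1 else 0
  if (is.null(KRange)) KRange <- defaultKRange(system)
  if (length(KRange) == 1L) KRange <- rep(KRange, 2L)
  if (is.null(params)) params <- defaultScoringParams(system)
  if (nTrials < 2L) stop("need at least 2 trials per condition")
  grid <- expand.grid(L = L, snrDb = snrDb, dynEps = dynEps)
  out <- list()
  allScores <- list()
  for (g in seq_len(nrow(grid))) {
    scored <- detectionScores(system, grid$L[g], nTrials, grid$snrDb[g],
                              grid$dynEps[g], KRange, methods, params,
                              seed = childSeed(seed, g), templates,
                              ranges = ranges, ...)
    if (keepScores) {
      scored$L <- grid$L[g]
      scored$dynEps <- grid$dynEps[g]
      allScores[[g]] <- scored
    }
    for (m in methods) {
      sm <- scored[scored$method == m, ]
      auc <- rocAuc(sm$score, sm$truth)
      ci <- aucBootstrapCI(sm$score, sm$truth, nBoot = nBoot,
                           seed = childSeed(seed, 1000L + g))
      out[[length(out) + 1L]] <- data.frame(
        system = system, L = grid$L[g], snrDb = grid$snrDb[g],
        dynEps = grid$dynEps[g], method = m, auc = auc, ci_low = ci[1L],
        ci_high = ci[2L], n_scores = nrow(sm), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (keepScores) attr(res, "scores") <- do.call(rbind, allScores)
  res
}

#' Default experiment ranges
#'
#' The package's declared study conditions for the detection experiments:
#' per-trial edge strengths are drawn uniformly from `defaultKRange`
#' (spanning barely detectable to strong coupling for each system), and the
#' dynamical-noise sweep runs over `defaultDynEpsSweep`, whose top value is
#' where per-step state perturbations become a substantial fraction of the
#' signal scale and detection degrades toward chance.
#'
#' @param system `"LM"`, `"VDP"`, or `"AR"`.
#' @return A numeric range (`defaultKRange`) or sweep vector
#'   (`defaultDynEpsSweep`).
#' @export
defaultKRange <- function(system) {
  switch(system, LM = c(0.02, 0.3), VDP = c(0.02, 0.3), AR = c(0.1, 0.6))
}

#' @rdname defaultKRange
#' @export
defaultDynEpsSweep <- function(system) {
  switch(system,
    LM = c(0, 0.005, 0.01, 0.02, 0.04),
    VDP = c(0, 0.2, 0.4, 0.6, 0.8),
    AR = 1)
}

defaultScoringParams <- function(system) {
  switch(system,
    LM = EmbeddingParams(2L, 1L),
    VDP = EmbeddingParams(3L, 5L),
    AR = EmbeddingParams(3L, 1L))
}

# Simulate + score one detection condition; returns the pooled long table.
detectionScores <- function(system, L, nTrials, snrDb, dynEps, KRange,
                            methods, params, seed, templates,
                            ranges = list(), ...) {
  topoCycle <- rep_len(templates, nTrials)
  res <- vector("list", nTrials * length(methods))
  ix <- 0L
  for (tr in seq_len(nTrials)) {
    trialSeed <- childSeed(seed, tr)
    K <- withSeed(childSeed(trialSeed, 1L),
                  runif(1, KRange[1L], KRange[2L]))
    spec <- makeTopologies("three_var", K = K, system = system,
                           templates = topoCycle[tr])[[1L]]
    spec <- randomizeSystemParams(spec, seed = childSeed(trialSeed, 2L),
                                  ranges = ranges)
    trial <- simulateTrial(spec, L,
                           NoiseSpec(snrDb = snrDb, dynEps = dynEps,
                                     seed = childSeed(trialSeed, 3L)), ...)
    truth <- truthMatrix(trial)
    labs <- channelNames(trialSeries(trial))
    for (m in methods) {
      sc <- scoreAllPairs(trialSeries(trial), method = m, params = params,
                          seed = childSeed(trialSeed, 4L))
      sc$truth <- truth[cbind(match(sc$source, labs), match(sc$target, labs))]
      sc$trial <- tr
      ix <- ix + 1L
      res[[ix]] <- sc
    }
  }
  do.call(rbind, res[seq_len(ix)])
}

#' Relative bidirectional coupling strength: Spearman correlation
#'
#' Simulates bidirectionally coupled two-variable systems across a grid of
#' independent `(K_xy, K_yx)` strengths and correlates the signed estimated
#' difference `score(x->y) - score(y->x)` with the signed generating
#' difference `K_xy - K_yx` (Spearman, so only monotonicity is tested).
#' A correlation near 1 means the method orders both the magnitude and the
#' direction of asymmetric coupling correctly; a negative value means it
#' systematically misidentifies the direction.
#'
#' @param system `"LM"`, `"VDP"`, or `"AR"`.
#' @param KGrid vector of strengths; the grid is `KGrid x KGrid`.
#' @param L series length (default 400).
#' @param nTrials trials per grid cell.
#' @param method `"CCS"` or `"CCM"`.
#' @param snrDb,dynEps noise settings.
#' @param params shared embedding parameters (system default when NULL).
#' @param seed master seed.
#' @param nBoot bootstrap resamples for the CI.
#' @param ... passed to the simulator.
#' @return A list: `rho`, `ci_low`, `ci_high`, and the per-trial table
#'   `scores` (columns `K_xy`, `K_yx`, `score_xy`, `score_yx`).
#' @export
relativeStrengthCorrelation <- function(system = "LM", KGrid, L = 400L,
                                        nTrials = 2L, method = "CCS",
                                        snrDb = Inf, dynEps = NULL,
                                        params = NULL, seed = 1L,
                                        nBoot = 1000L, ...) {
  if (is.null(dynEps)) dynEps <- if (system == "AR") 1 else 0
  if (is.null(params)) params <- defaultScoringParams(system)
  cells <- expand.grid(K_xy = KGrid, K_yx = KGrid)
  rows <- list()
  for (cl in seq_len(nrow(cells))) {
    for (tr in seq_len(nTrials)) {
      s <- childSeed(seed, cl * 10000L + tr)
      spec <- makeTopologies("two_var",
                             K = c(cells$K_xy[cl], cells$K_yx[cl]),
                             system = system)[[1L]]
      spec <- randomizeSystemParams(spec, seed = childSeed(s, 1L))
      trial <- simulateTrial(spec, L,
                             NoiseSpec(snrDb, dynEps, childSeed(s, 2L)), ...)
      sc <- scoreAllPairs(trialSeries(trial), method = method,
                          params = params, seed = childSeed(s, 3L))
      rows[[length(rows) + 1L]] <- data.frame(
        K_xy = cells$K_xy[cl], K_yx = cells$K_yx[cl],
        score_xy = sc$score[sc$source == "x"],
        score_yx = sc$score[sc$source == "y"])
    }
  }
  tab <- do.call(rbind, rows)
  dK <- tab$K_xy - tab$K_yx
  dS <- tab$score_xy - tab$score_yx
  if (sd(dS) == 0 || sd(dK) == 0)
    return(list(rho = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                scores = tab,
                note = "constant differences: correlation undefined"))
  rho <- cor(dS, dK, method = "spearman")
  boot <- withSeed(childSeed(seed, 424243L),
    vapply(seq_len(nBoot), function(b) {
      i <- sample.int(nrow(tab), replace = TRUE)
      if (sd(dS[i]) == 0 || sd(dK[i]) == 0) return(NA_real_)
      cor(dS[i], dK[i], method = "spearman")
    }, numeric(1)))
  ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE)
  list(rho = rho, ci_low = unname(ci[1L]), ci_high = unname(ci[2L]),
       scores = tab)
}

#' Unidirectional-coupling sweep
#'
#' Holds `K_xy = 0` and sweeps `K_yx`, asking whether a method can tell
#' strong unidirectional coupling from bidirectional coupling: the score for
#' the non-existent direction x -> y should stay near zero while y -> x
#' grows. For every grid point and method a Welch t-test compares the two
#' score distributions, with Benjamini-Hochberg correction across the grid.
#'
#' @param system `"LM"`, `"VDP"`, or `"AR"`.
#' @param KyxGrid vector of `K_yx` values (with `K_xy` fixed at 0).
#' @param L series length (default 400).
#' @param nTrials trials per grid point.
#' @param methods methods to evaluate.
#' @param snrDb,dynEps noise settings.
#' @param params shared embedding parameters.
#' @param seed master seed.
#' @param ... passed to the simulator.
#' @return A list: `summary` (per K and method: mean and 95% CI of each
#'   direction, `p_value`, BH-adjusted `p_adj`, `significant`) and the
#'   per-trial `scores` table.
#' @export
unidirectionalSweep <- function(system = "LM", KyxGrid, L = 400L,
                                nTrials = 50L, methods = c("CCS", "CCM"),
                                snrDb = Inf, dynEps = NULL, params = NULL,
                                seed = 1L, ...) {
  if (is.null(dynEps)) dynEps <- if (system == "AR") 1 else 0
  if (is.null(params)) params <- defaultScoringParams(system)
  rows <- list()
  for (ki in seq_along(KyxGrid)) {
    for (tr in seq_len(nTrials)) {
      s <- childSeed(seed, ki * 100003L + tr)
      spec <- makeTopologies("two_var", K = c(0, KyxGrid[ki]),
                             system = system)[[1L]]
      spec <- randomizeSystemParams(spec, seed = childSeed(s, 1L))
      trial <- simulateTrial(spec, L,
                             NoiseSpec(snrDb, dynEps, childSeed(s, 2L)), ...)
      for (m in methods) {
        sc <- scoreAllPairs(trialSeries(trial), method = m, params = params,
                            seed = childSeed(s, 3L))
        rows[[length(rows) + 1L]] <- data.frame(
          K_yx = KyxGrid[ki], method = m, trial = tr,
          score_xy = sc$score[sc$source == "x"],
          score_yx = sc$score[sc$source == "y"])
      }
    }
  }
  tab <- do.call(rbind, rows)
  summ <- list()
  for (m in methods) {
    for (kv in KyxGrid) {
      sub <- tab[tab$method == m & tab$K_yx == kv, ]
      tt <- tryCatch(t.test(sub$score_yx, sub$score_xy),
                     error = function(e) list(p.value = NA_real_))
      ciXY <- meanCI(sub$score_xy)
      ciYX <- meanCI(sub$score_yx)
      summ[[length(summ) + 1L]] <- data.frame(
        K_yx = kv, method = m, mean_xy = mean(sub$score_xy),
        xy_lo = ciXY[1L], xy_hi = ciXY[2L], mean_yx = mean(sub$score_yx),
        yx_lo = ciYX[1L], yx_hi = ciYX[2L], p_value = tt$p.value)
    }
  }
  summ <- do.call(rbind, summ)
  summ$p_adj <- NA_real_
  for (m in methods) {
    i <- summ$method == m
    summ$p_adj[i] <- p.adjust(summ$p_value[i], method = "BH")
  }
  summ$significant <- !is.na(summ$p_adj) & summ$p_adj < 0.05
  list(summary = summ, scores = tab)
}

meanCI <- function(x, level = 0.95) {
  if (length(x) < 2L || sd(x) == 0) return(c(mean(x), mean(x)))
  tt <- t.test(x, conf.level = level)
  as.numeric(tt$conf.int)
}
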
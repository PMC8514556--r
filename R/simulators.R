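#' Network topology templates
#'
#' Builds the transitive-free network templates used by the detection and
#' coupling-strength experiments. Three-variable detection networks must be
#' free of transitive causal relationships (a path i -> j -> k without a
#' direct i -> k edge), because an indirect influence makes the pairwise
#' ground truth ambiguous; requesting such a template is refused. The
#' available three-variable templates each carry two directed edges of equal
#' strength K: a common driver (Z -> X, Z -> Y), a common sink (X -> Z,
#' Y -> Z), and a bidirectional pair with a bystander (X <-> Y). The
#' two-variable template has independently adjustable strengths
#' `K[1] = K_xy` and `K[2] = K_yx`.
#'
#' @param kind `"three_var"` or `"two_var"`.
#' @param K for `"three_var"` a single shared edge strength; for
#'   `"two_var"` a length-2 vector `c(K_xy, K_yx)`.
#' @param system generating system tag stored in the specs ("LM", "VDP",
#'   "AR").
#' @param templates which three-variable templates to emit (any subset of
#'   `"common_driver"`, `"common_sink"`, `"bidirectional_pair"`).
#' @return A list of [NetworkSpec-class] objects.
#' @examples
#' couplingMatrix(makeTopologies("three_var", K = 0.2)[[1]])
#' @export
makeTopologies <- function(kind = c("three_var", "two_var"), K,
                           system = "LM",
                           templates = c("common_driver", "common_sink",
                                         "bidirectional_pair")) {
  kind <- match.arg(kind)
  if (any(K < 0)) stop("coupling strengths must be nonnegative")
  if (kind == "two_var") {
    if (length(K) != 2L) stop("two_var needs K = c(K_xy, K_yx)")
    Km <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
    Km["x", "y"] <- K[1L]
    Km["y", "x"] <- K[2L]
    return(list(NetworkSpec(Km, system, topologyTag = "two_var")))
  }
  transitive <- c("chain", "fan_out_chain", "fully_connected")
  bad <- intersect(templates, transitive)
  if (length(bad))
    stop("template(s) ", paste(bad, collapse = ", "), " contain transitive ",
         "causal relationships (an indirect path without a direct edge), ",
         "which make pairwise ground truth ambiguous; they are not ",
         "available for detection trials", call. = FALSE)
  templates <- match.arg(templates, several.ok = TRUE)
  if (length(K) != 1L) stop("three_var templates share a single K")
  vars <- c("X", "Y", "Z")
  build <- function(edges, tag) {
    Km <- matrix(0, 3, 3, dimnames = list(vars, vars))
    for (e in edges) Km[e[1L], e[2L]] <- K
    NetworkSpec(Km, system, topologyTag = tag)
  }
  defs <- list(
    common_driver = list(c("Z", "X"), c("Z", "Y")),
    common_sink = list(c("X", "Z"), c("Y", "Z")),
    bidirectional_pair = list(c("X", "Y"), c("Y", "X")))
  lapply(templates, function(tg) build(defs[[tg]], tg))
}

# Assemble the TrialResult from a finished simulation.
finishTrial <- function(values, spec, noise, labels, dt = 1) {
  series <- TimeSeries(values, dt = dt, labels = labels)
  if (is.finite(noise@snrDb))
    series <- addMeasurementNoise(series, noise@snrDb,
                                  seed = childSeed(noise@seed, 104729L))
  new("TrialResult", series = series, spec = spec, noise = noise,
      truth = couplingMatrix(spec) > 0)
}

#' Simulate coupled logistic maps
#'
#' Iterates the coupled quadratic map
#' `x_i(t+1) = x_i(t) * (r_i - r_i x_i(t) - sum_j K[j,i] x_j(t)) + eps_t`,
#' the standard coupled-logistic benchmark for state-space causal-inference
#' methods: deterministic, discrete, and chaotic for r in (3.6, 4).
#' Dynamical noise `eps_t ~ N(0, dynEps^2)` is added to each state, and any
#' state pushed out of (0, 1) — by noise, or by strong coupling when r is
#' near 4 — is clipped into the margin; a trajectory that becomes
#' non-finite is resampled with fresh initial conditions (up to
#' `maxRetries`, then an error reports the offending parameters).
#'
#' @param spec a [NetworkSpec-class] with `system = "LM"`;
#'   `systemParams$r` gives per-variable growth rates (default 3.8), and
#'   `systemParams$x0` optional initial conditions in (0, 1).
#' @param L number of retained samples (after burn-in).
#' @param noise a [NoiseSpec-class]; its seed drives everything random here.
#' @param burnIn discarded initial iterations (default 500).
#' @param maxRetries resampling attempts for divergent trajectories.
#' @return A [TrialResult-class].
#' @export
simulateLogisticMap <- function(spec, L, noise = NoiseSpec(), burnIn = 500L,
                                maxRetries = 20L) {
  stopifnot(L >= 2L)
  n <- spec@nVars
  K <- couplingMatrix(spec)
  r <- rep_len(spec@systemParams$r %||% 3.8, n)
  withSeed(noise@seed, {
    for (attempt in seq_len(maxRetries)) {
      x <- rep_len(spec@systemParams$x0 %||% runif(n, 0.2, 0.8), n)
      if (!is.null(spec@systemParams$x0) && attempt > 1L)
        x <- runif(n, 0.2, 0.8)
      out <- matrix(NA_real_, L, n)
      ok <- TRUE
      for (t in seq_len(burnIn + L)) {
        xn <- x * (r - r * x - as.numeric(crossprod(K, x)))
        if (any(!is.finite(xn))) {
          ok <- FALSE
          break
        }
        if (noise@dynEps > 0) xn <- xn + rnorm(n, 0, noise@dynEps)
        # strong coupling can push a state out of (0,1); clip into the margin
        xn <- pmin(pmax(xn, 1e-6), 1 - 1e-6)
        x <- xn
        if (t > burnIn) out[t - burnIn, ] <- x
      }
      if (ok) break
    }
    if (!ok)
      stop(sprintf(
        "logistic-map trajectory left (0,1) after %d retries (r = %s, max K = %g)",
        maxRetries, paste(signif(r, 3), collapse = ","), max(K)),
        call. = FALSE)
    finishTrial(out, spec, noise, rownames(K) %||% paste0("V", seq_len(n)))
  })
}

#' Simulate coupled Van der Pol oscillators
#'
#' Integrates the diffusively coupled Van der Pol system
#' `x''_i = mu_i (1 - x_i^2) x'_i - x_i + sum_j K[j,i] (x_j - x_i)`
#' (or direct forcing `+ sum_j K[j,i] x_j` with
#' `couplingForm = "direct"`) with fixed-step RK4 at `dtInt`, then keeps
#' every `sampleEvery`-th position sample: deterministic, continuous, and
#' approximately periodic, the regime where synchrony makes cross-mapping
#' hardest. Dynamical noise of magnitude `dynEps` is injected into the
#' velocity after every integration step, scaled by `sqrt(dtInt)` so the
#' effective noise intensity does not depend on the step size.
#'
#' @param spec a [NetworkSpec-class] with `system = "VDP"`;
#'   `systemParams$mu` gives per-oscillator stiffness (default 1.5).
#' @param L retained samples per channel.
#' @param noise a [NoiseSpec-class].
#' @param dtInt integration step (default 0.05 time units).
#' @param sampleEvery downsampling factor (default 4, so dt = 0.2).
#' @param burnInPeriods discarded initial stretch, in nominal limit-cycle
#'   periods of about 7 time units (default 50).
#' @param couplingForm `"diffusive"` (default) or `"direct"`.
#' @return A [TrialResult-class] of the observed positions.
#' @export
simulateVDP <- function(spec, L, noise = NoiseSpec(), dtInt = 0.05,
                        sampleEvery = 4L, burnInPeriods = 50,
                        couplingForm = c("diffusive", "direct")) {
  couplingForm <- match.arg(couplingForm)
  n <- spec@nVars
  K <- couplingMatrix(spec)
  mu <- rep_len(spec@systemParams$mu %||% 1.5, n)
  if (any(mu <= 0)) stop("oscillator stiffness mu must be positive")
  deriv <- function(x, v) {
    drive <- if (couplingForm == "diffusive")
      as.numeric(crossprod(K, x)) - colSums(K) * x
    else as.numeric(crossprod(K, x))
    list(dx = v, dv = mu * (1 - x^2) * v - x + drive)
  }
  burnSteps <- ceiling(burnInPeriods * 7 / dtInt)
  totalSteps <- burnSteps + L * sampleEvery
  withSeed(noise@seed, {
    x <- spec@systemParams$x0 %||% runif(n, -2, 2)
    v <- spec@systemParams$v0 %||% runif(n, -2, 2)
    out <- matrix(NA_real_, L, n)
    filled <- 0L
    noiseSd <- noise@dynEps * sqrt(dtInt)
    for (s in seq_len(totalSteps)) {
      k1 <- deriv(x, v)
      k2 <- deriv(x + dtInt / 2 * k1$dx, v + dtInt / 2 * k1$dv)
      k3 <- deriv(x + dtInt / 2 * k2$dx, v + dtInt / 2 * k2$dv)
      k4 <- deriv(x + dtInt * k3$dx, v + dtInt * k3$dv)
      x <- x + dtInt / 6 * (k1$dx + 2 * k2$dx + 2 * k3$dx + k4$dx)
      v <- v + dtInt / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
      if (noiseSd > 0) v <- v + rnorm(n, 0, noiseSd)
      if (any(!is.finite(x)) || any(!is.finite(v)))
        stop("Van der Pol state became non-finite (mu = ",
             paste(signif(mu, 3), collapse = ","), ", max K = ", max(K), ")",
             call. = FALSE)
      if (s > burnSteps && (s - burnSteps) %% sampleEvery == 0L) {
        filled <- filled + 1L
        out[filled, ] <- x
      }
    }
    finishTrial(out, spec, noise, rownames(K) %||% paste0("V", seq_len(n)),
                dt = dtInt * sampleEvery)
  })
}

#' Simulate coupled autoregressive models
#'
#' Generates the linear, stochastic benchmark:
#' `x_i(t) = sum_p a_{i,p} x_i(t-p) + sum_j K[j,i] x_j(t-1) + dynEps * e_t`
#' with standard-normal innovations `e_t`. The innovations are the
#' dynamical stochasticity of this system, scaled by `dynEps` (default 1
#' here, unlike the deterministic systems, since an AR model without
#' innovations decays to a constant). The joint coupled system must be
#' stable: the spectral radius of its companion matrix is checked and an
#' unstable system is an error.
#'
#' @param spec a [NetworkSpec-class] with `system = "AR"`;
#'   `systemParams$a` is a list of per-variable AR coefficient vectors
#'   (default AR(1) with a = 0.5).
#' @param L retained samples.
#' @param noise a [NoiseSpec-class]; `dynEps` scales the innovations.
#' @param burnIn discarded initial samples (default 500).
#' @return A [TrialResult-class].
#' @export
simulateAR <- function(spec, L, noise = NoiseSpec(dynEps = 1), burnIn = 500L) {
  n <- spec@nVars
  K <- couplingMatrix(spec)
  a <- spec@systemParams$a %||% rep(list(0.5), n)
  if (!is.list(a)) a <- rep(list(a), n)
  a <- rep_len(a, n)
  p <- max(vapply(a, length, integer(1)), 1L)
  # companion matrix of the joint VAR: lag-1 block gets the coupling
  A <- array(0, c(n, n, p))
  for (i in seq_len(n)) A[i, i, seq_along(a[[i]])] <- a[[i]]
  A[, , 1L] <- A[, , 1L] + t(K)  # K[j, i]: j -> i enters row i, column j
  comp <- matrix(0, n * p, n * p)
  for (l in seq_len(p)) comp[seq_len(n), (l - 1L) * n + seq_len(n)] <- A[, , l]
  if (p > 1L)
    comp[n + seq_len(n * (p - 1L)), seq_len(n * (p - 1L))] <-
      diag(n * (p - 1L))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf(
      "coupled AR system is unstable (spectral radius %.3f >= 1)", rho),
      call. = FALSE)
  withSeed(noise@seed, {
    hist <- matrix(0, p, n)
    out <- matrix(NA_real_, L, n)
    for (t in seq_len(burnIn + L)) {
      xn <- numeric(n)
      for (l in seq_len(p)) xn <- xn + A[, , l] %*% hist[l, ]
      xn <- as.numeric(xn) + noise@dynEps * rnorm(n)
      if (p > 1L) hist[2:p, ] <- hist[seq_len(p - 1L), ]
      hist[1L, ] <- xn
      if (t > burnIn) out[t - burnIn, ] <- xn
    }
    finishTrial(out, spec, noise, rownames(K) %||% paste0("V", seq_len(n)))
  })
}

#' Add Gaussian measurement noise at a given SNR
#'
#' Corrupts each channel with zero-mean Gaussian noise whose RMS equals
#' `RMS(signal) / 10^(snrDb/20)`, where the signal magnitude is the RMS of
#' the mean-removed channel (the informative fluctuation). `snrDb = Inf`
#' returns the input unchanged; a constant channel with finite SNR is an
#' error, since its noise scale would be zero.
#'
#' @param series a [TimeSeries-class].
#' @param snrDb signal-to-noise ratio in dB.
#' @param seed RNG seed.
#' @return A [TimeSeries-class] with noise added.
#' @export
addMeasurementNoise <- function(series, snrDb, seed = NULL) {
  if (!(snrDb >= 0)) stop("snrDb must be nonnegative (Inf allowed)")
  if (is.infinite(snrDb)) return(series)
  v <- tsValues(series)
  withSeed(seed, {
    for (ch in seq_len(ncol(v))) {
      sig <- rootMeanSquare(v[, ch] - mean(v[, ch]))
      if (sig == 0)
        stop("channel ", ch, " has zero variance; SNR undefined",
             call. = FALSE)
      v[, ch] <- v[, ch] + rnorm(nrow(v), 0, sig / 10^(snrDb / 20))
    }
    TimeSeries(v, dt = samplingInterval(series),
               labels = channelNames(series))
  })
}

#' Draw a network spec with randomized intrinsic parameters
#'
#' Detection trials vary the intrinsic dynamics from trial to trial; this
#' helper attaches parameters drawn from the package's default uniform
#' ranges (growth rate r in (3.6, 4) for logistic maps, stiffness mu in
#' (0.5, 2.5) for Van der Pol, AR(1) coefficient in (0.2, 0.9)) to a
#' topology template.
#'
#' @param spec a [NetworkSpec-class] template (from [makeTopologies()]).
#' @param seed RNG seed for the parameter draw.
#' @param ranges optional overrides: list with entries `r`, `mu`, `a`
#'   (each a length-2 range).
#' @return The spec with `systemParams` filled.
#' @export
randomizeSystemParams <- function(spec, seed = NULL, ranges = list()) {
  n <- spec@nVars
  withSeed(seed, {
    sp <- switch(spec@system,
      LM = list(r = runif(n, (ranges$r %||% c(3.6, 4.0))[1L],
                          (ranges$r %||% c(3.6, 4.0))[2L])),
      VDP = list(mu = runif(n, (ranges$mu %||% c(0.5, 2.5))[1L],
                            (ranges$mu %||% c(0.5, 2.5))[2L])),
      AR = list(a = as.list(runif(n, (ranges$a %||% c(0.2, 0.9))[1L],
                                  (ranges$a %||% c(0.2, 0.9))[2L]))))
    initialize(spec, systemParams = sp)
  })
}

#' Dispatch a trial to the simulator for its system
#'
#' @param spec a [NetworkSpec-class].
#' @param L retained samples.
#' @param noise a [NoiseSpec-class].
#' @param ... passed on to the system's simulator.
#' @return A [TrialResult-class].
#' @export
simulateTrial <- function(spec, L, noise = NoiseSpec(), ...) {
  switch(spec@system,
    LM = simulateLogisticMap(spec, L, noise, ...),
    VDP = simulateVDP(spec, L, noise, ...),
    AR = simulateAR(spec, L, noise, ...),
    stop("unknown system '", spec@system, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
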
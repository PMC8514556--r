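# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct formulas, and a
# self-contained Lorenz integrator.

# Brute-force rank/error recomputation from raw coordinate matrices:
# all unordered index pairs, plain loops, base rank().
bruteForceRankErr <- function(px, py, exclusionWindow = 0L) {
  n <- nrow(px)
  pairs <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (abs(i - j) > exclusionWindow) pairs[[length(pairs) + 1L]] <- c(i, j)
  dx <- vapply(pairs, function(p) sqrt(sum((px[p[1L], ] - px[p[2L], ])^2)),
               numeric(1))
  dy <- vapply(pairs, function(p) sqrt(sum((py[p[1L], ] - py[p[2L], ])^2)),
               numeric(1))
  rx <- rank(dx)
  ry <- rank(dy)
  list(rankX = rx, rankY = ry, err = rx - ry,
       pairs = do.call(rbind, pairs))
}

# Exhaustive expected squared rank difference over all permutation pairs.
enumerateNullErr2 <- function(n) {
  perms <- permEnum(seq_len(n))
  tot <- 0
  for (a in perms) for (b in perms) tot <- tot + mean((a - b)^2)
  tot / length(perms)^2
}

permEnum <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(permEnum(x[-i]), function(p) c(x[i], p)))
  out
}

# Fixed-step RK4 Lorenz trajectory (classic sigma/rho/beta), returning the
# full 3-d state so delay reconstructions can be compared with truth.
lorenzTrajectory <- function(n, dt = 0.02, skip = 500L,
                             state = c(1, 1, 20)) {
  f <- function(s) c(10 * (s[2] - s[1]),
                     s[1] * (28 - s[3]) - s[2],
                     s[1] * s[2] - 8 / 3 * s[3])
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(skip + n)) {
    k1 <- f(state)
    k2 <- f(state + dt / 2 * k1)
    k3 <- f(state + dt / 2 * k2)
    k4 <- f(state + dt * k3)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i > skip) out[i - skip, ] <- state
  }
  out
}

# Two-channel TimeSeries of independent Gaussian noise.
noisePair <- function(L, seed) {
  set.seed(seed)
  TimeSeries(cbind(x = rnorm(L), y = rnorm(L)))
}

lmParams <- EmbeddingParams(2, 1)
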
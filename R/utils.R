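# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit integer range.
childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483647L)
}

rootMeanSquare <- function(x) sqrt(mean(x^2))

# z-score one channel; constant channels are left centered at 0.
zScore <- function(x) {
  s <- sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

# Extract channel `channel` (index or name) of a TimeSeries as a vector.
tsChannel <- function(ts, channel = 1L) {
  v <- tsValues(ts)
  if (is.character(channel)) {
    if (!channel %in% colnames(v))
      stop("unknown channel '", channel, "'", call. = FALSE)
  }
  as.numeric(v[, channel])
}

# Ordered-pair labels "a->b" for all directed pairs of `n` channels.
directedPairNames <- function(labels) {
  n <- length(labels)
  out <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    out <- c(out, paste0(labels[i], "->", labels[j]))
  out
}

# All ordered index pairs (i, j), i != j, row-wise.
directedPairIndices <- function(n) {
  idx <- expand.grid(target = seq_len(n), source = seq_len(n))
  idx <- idx[idx$source != idx$target, c("source", "target")]
  idx <- idx[order(idx$source, idx$target), ]
  rownames(idx) <- NULL
  as.matrix(idx)
}
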
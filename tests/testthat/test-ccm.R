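test_that("cross-map estimates average neighbors with exponential weights", {
  # hand-built 2-d embedding: target point at origin, neighbors at
  # distances 1, 2, 4 (plus one excluded temporal neighbor)
  pts <- rbind(c(0, 0), c(1, 0), c(0, 2), c(4, 0), c(0.1, 0))
  # the closest point (row 5) is a temporal neighbor and must be excluded
  emb <- new("DelayEmbedding", points = pts, times = c(1L, 5L, 9L, 13L, 2L),
             params = EmbeddingParams(2, 1))
  yv <- c(10, 1, 2, 3, 99)
  est <- crossMapEstimate(emb, yv, t = 1, k = 3, exclusionWindow = 3)
  w <- exp(-c(1, 2, 4) / 1)
  w <- w / sum(w)
  expect_equal(est, sum(w * c(1, 2, 3)))

  # equal distances -> uniform weights -> plain mean
  ptsEq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0))
  embEq <- new("DelayEmbedding", points = ptsEq, times = 1:4,
               params = EmbeddingParams(2, 1))
  expect_equal(crossMapEstimate(embEq, c(0, 3, 6, 9), t = 1, k = 3),
               mean(c(3, 6, 9)))

  # exact match collapses the weight onto it
  ptsZero <- rbind(c(0, 0), c(0, 0), c(5, 5), c(6, 6))
  embZero <- new("DelayEmbedding", points = ptsZero, times = 1:4,
                 params = EmbeddingParams(2, 1))
  expect_equal(crossMapEstimate(embZero, c(0, 7, 1, 2), t = 1, k = 1), 7)

  expect_error(crossMapEstimate(emb, yv, t = 1, k = 5, exclusionWindow = 3),
               "admissible")
})

test_that("cross-map weights are nonnegative and sum to one", {
  set.seed(14)
  emb <- delayEmbed(rnorm(40), lmParams)
  maps <- crosssort:::crossMapWeights(emb, k = 3, exclusionWindow = 2)
  expect_true(all(maps$w >= 0))
  expect_equal(rowSums(maps$w), rep(1, nrow(maps$w)))
})

test_that("self cross-map of a chaotic trace is essentially perfect", {
  fx <- makeFixture("identical-pair", seed = 10, L = 200)
  s <- ccm(fx, params = lmParams)
  expect_gte(scoreValue(s$x_to_y), 0.999)
  expect_gte(scoreValue(s$y_to_x), 0.999)
})

test_that("independent noise cross-maps to nothing", {
  scores <- sapply(1:40, function(i) {
    s <- ccm(noisePair(400, seed = 4000 + i), params = lmParams)
    c(scoreValue(s$x_to_y), scoreValue(s$y_to_x))
  })
  expect_lt(abs(mean(scores)), 0.07)
})

test_that("cross-map skill converges with library length", {
  # the convergence property: mean skill for a coupled pair is higher at
  # long L than short L
  meanAt <- function(L) {
    mean(sapply(1:20, function(i) {
      tr <- makeFixture("lm-unidirectional", seed = 600 + i, L = L)
      sc <- scoreAllPairs(trialSeries(tr), "CCM", lmParams)
      sc$score[sc$source == "x"]  # the true direction
    }))
  }
  m <- c(meanAt(50), meanAt(100), meanAt(400))
  expect_lt(m[1], m[3])
  expect_lt(m[2], m[3])
})

test_that("ccm and scoreAllPairs agree on the direction convention", {
  tr <- makeFixture("lm-unidirectional", seed = 12, L = 300)
  x <- tsValues(trialSeries(tr))[, 1]
  y <- tsValues(trialSeries(tr))[, 2]
  viaPair <- ccm(x, y, params = lmParams)
  viaAll <- scoreAllPairs(trialSeries(tr), "CCM", lmParams)
  expect_equal(scoreValue(viaPair$x_to_y),
               viaAll$score[viaAll$source == "x"], tolerance = 1e-12)
  expect_equal(scoreValue(viaPair$y_to_x),
               viaAll$score[viaAll$source == "y"], tolerance = 1e-12)
  # x drives y here, so the true direction must dominate
  expect_gt(scoreValue(viaPair$x_to_y), scoreValue(viaPair$y_to_x))
})
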
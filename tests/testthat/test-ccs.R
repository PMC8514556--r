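test_that("identical embeddings give identical distance ranks", {
  set.seed(2)
  emb <- delayEmbed(rnorm(30), lmParams)
  rc <- pairwiseRankDistances(emb, emb, exclusionWindow = 0)
  expect_equal(rc@rankX, rc@rankY)
})

test_that("rank vectors follow the distance order, pairs aligned", {
  # 1-d points 0,1,3: pair distances (1,2),(1,3),(2,3) -> 1,3,2; reversing
  # the distance order in the second manifold reverses only its ranks
  px <- delayEmbed(c(0, 1, 3), EmbeddingParams(1, 1))
  py <- delayEmbed(c(0, 3, 4), EmbeddingParams(1, 1))  # dists 3,4,1
  rc <- pairwiseRankDistances(px, py, exclusionWindow = 0)
  expect_equal(rc@pairIndex, cbind(c(1, 1, 2), c(2, 3, 3)))
  expect_equal(rc@rankX, rank(c(1, 3, 2)))
  expect_equal(rc@rankY, rank(c(3, 4, 1)))
})

test_that("ranks are invariant under order-preserving coordinate maps", {
  pts <- c(0, 1, 2.5, 7)
  a <- delayEmbed(pts, EmbeddingParams(1, 1))
  b <- delayEmbed(pts * 5 + 7, EmbeddingParams(1, 1))
  rc <- pairwiseRankDistances(a, b, exclusionWindow = 0)
  expect_equal(rc@rankX, rc@rankY)
})

test_that("temporal exclusion and degeneracy rules are enforced", {
  emb <- delayEmbed(sin(1:20), lmParams)
  rc <- pairwiseRankDistances(emb, emb, exclusionWindow = 3)
  expect_true(all(abs(rc@pairIndex[, 1] - rc@pairIndex[, 2]) > 3))
  flat <- delayEmbed(rep(1, 20), lmParams)
  expect_error(pairwiseRankDistances(flat, emb, exclusionWindow = 0),
               "degenerate")
  expect_error(pairwiseRankDistances(emb, emb, exclusionWindow = 19),
               "fewer than 2")
})

test_that("rank errors order by the conditioning manifold's ranks", {
  rc <- new("RankCorrespondence", rankX = c(1, 2, 3), rankY = c(2, 1, 3),
            nPairs = 3L, pairIndex = cbind(1:3, 2:4))
  expect_equal(rankError(rc, "x_to_y"), c(1, -1, 0))
  expect_equal(rankError(rc, "y_to_x"), c(-1, 1, 0))

  idem <- new("RankCorrespondence", rankX = c(1, 2, 3), rankY = c(1, 2, 3),
              nPairs = 3L, pairIndex = cbind(1:3, 2:4))
  expect_equal(rankError(idem, "x_to_y"), c(0, 0, 0))

  # full reversal of N ranks: error at conditioning rank r is (N+1-r) - r
  N <- 7
  rev <- new("RankCorrespondence", rankX = 1:N, rankY = N:1,
             nPairs = as.integer(N), pairIndex = cbind(1:N, 2:(N + 1)))
  expect_equal(rankError(rev, "x_to_y"), (N + 1 - 1:N) - 1:N)
})

test_that("null expectation matches brute-force permutation enumeration", {
  for (n in 2:4)
    expect_equal(nullErr2(n), enumerateNullErr2(n))
  expect_equal(nullErr2(3), 4 / 3)
  expect_equal(nullErr2(2), 1 / 2)
  # conditional: average (R_X - r)^2 over uniform R_X
  for (n in c(3, 5)) for (r in 1:n)
    expect_equal(nullErr2(n, "conditional", rank = r), mean((1:n - r)^2))
  expect_equal(nullErr2(5, "conditional", rank = 3), 2)
  expect_error(nullErr2(5, "conditional"), "requires")
})

test_that("the cumulative normalized error curve is as defined", {
  perfect <- nerr2Curve(rep(0, 5), null = 4)
  expect_equal(perfect@cumNerr2, rep(1, 5))
  chance <- nerr2Curve(rep(2, 5), null = 4)
  expect_equal(chance@cumNerr2, rep(0, 5))
  mixed <- nerr2Curve(c(0, sqrt(4), 0), null = 4)
  expect_equal(mixed@cumNerr2, c(1, 1 / 2, 2 / 3))
  expect_equal(mixed@rankGrid, c(1, 2, 3) / 3)
  expect_error(nerr2Curve(numeric(0), 1), "empty")
})

test_that("curve-fit score recovers intercepts", {
  grid <- seq_len(100) / 100
  flatOne <- new("ErrorCurve", rankGrid = grid, cumNerr2 = rep(1, 100),
                 nullValue = 1)
  expect_equal(ccsScoreFromCurve(flatOne)$value, 1, tolerance = 1e-6)
  flatZero <- new("ErrorCurve", rankGrid = grid, cumNerr2 = rep(0, 100),
                  nullValue = 1)
  expect_equal(ccsScoreFromCurve(flatZero)$value, 0, tolerance = 1e-6)
  synth <- new("ErrorCurve", rankGrid = grid,
               cumNerr2 = 0.6 * exp(-3 * grid) + 0.2, nullValue = 1)
  fit <- ccsScoreFromCurve(synth, maxRankFrac = 1)
  expect_true(fit$fitOk)
  expect_equal(fit$value, 0.8, tolerance = 1e-6)
  expect_error(ccsScoreFromCurve(synth, maxRankFrac = 0.02), "maxRankFrac")
})

test_that("rank/ERR pipeline matches an exhaustive brute-force oracle", {
  set.seed(9)
  for (rep in 1:5) {
    x <- rnorm(5)
    y <- rnorm(5)
    ex <- delayEmbed(x, EmbeddingParams(2, 1))
    ey <- delayEmbed(y, EmbeddingParams(2, 1))
    rc <- pairwiseRankDistances(ex, ey, exclusionWindow = 0)
    oracle <- bruteForceRankErr(embeddingPoints(ex), embeddingPoints(ey))
    expect_equal(sort(rc@rankX), sort(oracle$rankX))
    expect_equal(rc@rankX - rc@rankY, oracle$err)
    expect_equal(sort(rankError(rc, "x_to_y")), sort(oracle$err))
    # conditioning order: errors sorted by the driven manifold's ranks
    expect_equal(rankError(rc, "x_to_y"), oracle$err[order(oracle$rankY)])
    expect_equal(rankError(rc, "y_to_x"), oracle$err[order(oracle$rankX)])
  }
})

test_that("identical series score as maximal and direction-symmetric", {
  fx <- makeFixture("identical-pair", seed = 4, L = 400)
  s <- ccs(fx, params = lmParams)
  expect_gt(scoreValue(s$x_to_y), 0.95)
  expect_gt(scoreValue(s$y_to_x), 0.95)
  expect_equal(scoreValue(s$x_to_y), scoreValue(s$y_to_x))
})

test_that("scores stay in [-1, 1] and the curve stays below 1", {
  set.seed(31)
  for (rep in 1:6) {
    x <- rnorm(60)
    y <- 0.5 * x + rnorm(60)
    rc <- pairwiseRankDistances(delayEmbed(x, lmParams),
                                delayEmbed(y, lmParams),
                                exclusionWindow = 2)
    err <- rankError(rc, "x_to_y")
    curve <- nerr2Curve(err, nullErr2(rc@nPairs, "conditional",
                                     rank = sort(rc@rankY)))
    expect_lte(max(curve@cumNerr2), 1)
    s <- ccs(x, y, params = lmParams)
    expect_true(all(abs(c(scoreValue(s$x_to_y), scoreValue(s$y_to_x))) <= 1))
  }
})

test_that("the CCS score is invariant under affine coordinate distortion", {
  tr <- makeFixture("lm-unidirectional", seed = 6, L = 200)
  x <- tsValues(trialSeries(tr))[, 1]
  y <- tsValues(trialSeries(tr))[, 2]
  base <- ccs(x, y, params = lmParams, normalize = FALSE)
  warped <- ccs(x * 12 - 3, y * 0.2 + 40, params = lmParams,
                normalize = FALSE)
  expect_equal(scoreValue(base$x_to_y), scoreValue(warped$x_to_y))
  expect_equal(scoreValue(base$y_to_x), scoreValue(warped$y_to_x))
})

test_that("surrogate significance uses the plus-one estimator", {
  fx <- makeFixture("identical-pair", seed = 8, L = 250)
  s <- ccsSignificance(fx, params = lmParams, nSurrogates = 19, seed = 2)
  expect_equal(pValue(s), 1 / 20)
  expect_error(ccsSignificance(fx, params = lmParams, nSurrogates = 5),
               "at least 19")
})

test_that("coupled-pair scores degrade monotonically with measurement noise", {
  snrs <- c(Inf, 20, 10)
  means <- sapply(seq_along(snrs), function(si) {
    mean(sapply(1:25, function(i) {
      spec <- makeTopologies("two_var", K = c(0.3, 0))[[1]]
      tr <- simulateLogisticMap(spec, 300,
                                NoiseSpec(snrDb = snrs[si], seed = 900 + i))
      sc <- scoreAllPairs(trialSeries(tr), "CCS", lmParams)
      sc$score[sc$source == "x"]
    }))
  })
  expect_true(all(diff(means) < 0))
})
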
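test_that("cyclic canonicalization is idempotent and rotation-invariant", {
  s <- c(2L, 3L, 1L)
  expect_equal(canonicalCycle(s), c(1L, 2L, 3L))
  expect_equal(canonicalCycle(canonicalCycle(s)), canonicalCycle(s))
  rotations <- lapply(1:3, function(r)
    s[((seq_len(3) + r - 2L) %% 3L) + 1L])
  canon <- lapply(rotations, canonicalCycle)
  expect_length(unique(canon), 1)
  # ties inside the sequence
  expect_equal(canonicalCycle(c(2L, 1L, 2L, 1L)), c(1L, 2L, 1L, 2L))
})

test_that("cyclic class count matches direct enumeration", {
  for (k in 2:5) {
    all3 <- expand.grid(a = 1:k, b = 1:k, c = 1:k)
    canon <- apply(all3, 1, function(s)
      paste(canonicalCycle(as.integer(s)), collapse = "-"))
    expect_equal(crosssort:::countCyclicClasses(k, 3),
                 length(unique(canon)))
  }
})

test_that("windowed scoring tracks a scripted coupling switch", {
  off <- matrix(0, 3, 3)
  on <- off; on[1, 2] <- 0.6; on[1, 3] <- 0.6
  sim <- regimeSwitchTriad(list(off, on), schedule = rep(c(1L, 2L), 3),
                           segmentLen = 120, noise = NoiseSpec(seed = 6))
  ws <- windowedCCS(sim$series, epochLen = 120, windowLen = 120,
                    params = EmbeddingParams(3, 2))
  sc <- windowScores(ws)
  drive <- sc[, 1, 1:2]  # OB->CA and OB->AMG, the scripted edges
  offMean <- mean(drive[sim$schedule == 1L, ])
  onMean <- mean(drive[sim$schedule == 2L, ])
  expect_gt(onMean, offMean)
})

test_that("identical channels give maximal windowed scores", {
  set.seed(33)
  x <- as.numeric(arima.sim(list(ar = 0.8), 300))
  ts3 <- TimeSeries(cbind(a = x, b = x, c = x))
  ws <- windowedCCS(ts3, epochLen = 150, windowLen = 90,
                    params = EmbeddingParams(2, 1))
  expect_true(all(windowScores(ws) > 0.9))
  expect_equal(dim(windowScores(ws)), c(2, 3, 6))
})

test_that("window length checks name the minimum", {
  set.seed(1)
  ts3 <- TimeSeries(matrix(rnorm(300), ncol = 3))
  expect_error(windowedCCS(ts3, epochLen = 50, windowLen = 8,
                           params = EmbeddingParams(3, 2)),
               "window too short")
})

test_that("k-means state clustering separates well-separated blobs", {
  centroids <- rbind(rep(0.8, 6), rep(-0.6, 6))
  sched <- matrix(rep(c(1L, 2L), each = 30), 20, 3)
  syn <- syntheticWindowedScores(centroids, sched, noiseSd = 0.03, seed = 4)
  cl <- clusterStates(syn$ws, k = 2, seed = 9)
  agree <- mean(stateLabels(cl$states) == syn$schedule)
  expect_true(agree %in% c(0, 1))  # perfect up to label swap
  # determinism under the same seed
  cl2 <- clusterStates(syn$ws, k = 2, seed = 9)
  expect_identical(cl$centroids, cl2$centroids)
})

test_that("back-transformed centroids equal cluster means in score units", {
  set.seed(12)
  centroids <- matrix(runif(5 * 6, -0.5, 1), 5, 6)
  sched <- matrix(sample(1:5, 40 * 3, replace = TRUE), 40, 3)
  syn <- syntheticWindowedScores(centroids, sched, noiseSd = 0.05, seed = 2)
  cl <- clusterStates(syn$ws, k = 5, seed = 3)
  flat <- matrix(windowScores(syn$ws), 120, 6)
  means <- t(sapply(1:5, function(g) colMeans(flat[cl$assignments == g, ])))
  expect_equal(unname(cl$centroids), unname(means), tolerance = 1e-8)
})

test_that("scripted five-regime scores are recovered by clustering", {
  set.seed(7)
  centroids <- rbind(
    c(0.9, 0.9, 0.8, 0.8, 0.7, 0.7),
    c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
    c(0.9, 0.1, 0.9, 0.1, 0.0, 0.0),
    c(-0.3, 0.5, 0.2, 0.8, -0.2, 0.4),
    c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  noiseSd <- 0.08
  sched <- matrix(sample(1:5, 120 * 3, replace = TRUE), 120, 3)
  syn <- syntheticWindowedScores(centroids, sched, noiseSd = noiseSd,
                                 seed = 11)
  cl <- clusterStates(syn$ws, k = 5, seed = 13)
  m <- matchCentroids(cl$centroids, centroids)
  expect_lt(m$rmse, noiseSd)
})

test_that("sequence statistics count cyclic classes per condition", {
  labels <- rbind(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L),
                  c(1L, 1L, 2L))
  st <- new("StateSequences", labels = labels, k = 3L,
            epochLabels = rep("a", 4))
  stats <- sequenceStatistics(st)
  expect_equal(stats$pattern[1], "1-2-3")
  expect_equal(stats$count[1], 3)
  expect_equal(stats$pct[1], 75)
  # binomial SE of the percentage
  expect_equal(stats$se_pct[1], 100 * sqrt(0.75 * 0.25 / 4))
})

test_that("uniform random sequences show no extreme patterns", {
  set.seed(19)
  worst <- sapply(1:40, function(i) {
    labels <- matrix(sample(1:5, 200 * 3, replace = TRUE), 200, 3)
    st <- new("StateSequences", labels = labels, k = 5L,
              epochLabels = rep("null", 200))
    max(sequenceStatistics(st)$neg_log10_p)
  })
  expect_gte(mean(worst < 2), 0.95)
})
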
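test_that("delay embedding builds the documented delay vectors", {
  emb <- delayEmbed(1:5, EmbeddingParams(2, 1))
  expect_equal(embeddingPoints(emb),
               rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  expect_equal(embeddingTimes(emb), 1:4)

  emb2 <- delayEmbed(1:6, EmbeddingParams(3, 2))
  expect_equal(embeddingPoints(emb2), rbind(c(1, 3, 5), c(2, 4, 6)))

  constant <- delayEmbed(rep(3, 10), EmbeddingParams(3, 2))
  expect_true(all(dist(embeddingPoints(constant)) == 0))
})

test_that("embedding point count is L - (D-1)*lag for all valid shapes", {
  set.seed(5)
  for (rep in 1:20) {
    L <- sample(10:60, 1)
    D <- sample(1:4, 1)
    tau <- sample(1:3, 1)
    if ((D - 1) * tau >= L) next
    emb <- delayEmbed(rnorm(L), EmbeddingParams(D, tau))
    expect_equal(nrow(embeddingPoints(emb)), L - (D - 1) * tau)
  }
})

test_that("series too short for the requested embedding is an error", {
  expect_error(delayEmbed(1:4, EmbeddingParams(3, 2)), "too short")
})

test_that("embedding a shifted series yields the same shifted point set", {
  set.seed(11)
  x <- rnorm(60)
  p <- EmbeddingParams(3, 2)
  a <- embeddingPoints(delayEmbed(x, p))
  b <- embeddingPoints(delayEmbed(x[6:60], p))
  expect_equal(b, a[6:nrow(a), ])
})

test_that("lag selection lands near the quarter period of a sine", {
  x <- sin(2 * pi * (1:400) / 40)
  p <- selectEmbeddingParams(x, maxDim = 5, maxLag = 30)
  expect_gte(embeddingLag(p), 8)
  expect_lte(embeddingLag(p), 12)
})

test_that("white noise never satisfies the neighbor criterion", {
  set.seed(3)
  x <- rnorm(300)
  expect_warning(p <- selectEmbeddingParams(x, maxDim = 3, maxLag = 10),
                 "never fell below")
  expect_equal(embeddingDim(p), 3)
})

test_that("explicit overrides bypass selection; constant input errors", {
  p <- selectEmbeddingParams(rnorm(50), dim = 3, lag = 2)
  expect_equal(embeddingDim(p), 3)
  expect_equal(embeddingLag(p), 2)
  expect_error(selectEmbeddingParams(rep(1, 50)), "constant")
})

test_that("delay reconstruction preserves the Lorenz attractor geometry", {
  # distances between temporally distant state-space points versus the same
  # pairs in a 3-d delay reconstruction of the x coordinate alone
  traj <- lorenzTrajectory(600)
  emb <- delayEmbed(traj[, 1], EmbeddingParams(3, 4))
  pts <- embeddingPoints(emb)
  n <- nrow(pts)
  set.seed(21)
  i <- sample(n, 400, replace = TRUE)
  j <- sample(n, 400, replace = TRUE)
  keep <- abs(i - j) > 50
  dTrue <- sqrt(rowSums((traj[i[keep], ] - traj[j[keep], ])^2))
  dEmb <- sqrt(rowSums((pts[i[keep], ] - pts[j[keep], ])^2))
  expect_gt(cor(dTrue, dEmb, method = "spearman"), 0.8)
})
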
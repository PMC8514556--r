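test_that("topology templates carry the right edges and refusals", {
  tops <- makeTopologies("three_var", K = 0.2)
  expect_length(tops, 3)
  cd <- tops[[1]]
  expect_equal(sum(couplingMatrix(cd) > 0), 2)
  expect_equal(couplingMatrix(cd)["Z", "X"], 0.2)
  expect_equal(couplingMatrix(cd)["Z", "Y"], 0.2)
  expect_error(makeTopologies("three_var", K = 0.2, templates = "chain"),
               "transitive")
  two <- makeTopologies("two_var", K = c(0.1, 0))[[1]]
  expect_equal(couplingMatrix(two)["x", "y"], 0.1)
  expect_equal(couplingMatrix(two)["y", "x"], 0)
  empty <- makeTopologies("two_var", K = c(0, 0))[[1]]
  expect_true(all(couplingMatrix(empty) == 0))
})

test_that("trial ground truth mirrors the coupling matrix", {
  tr <- simulateLogisticMap(makeTopologies("three_var", K = 0.15)[[1]], 50,
                            NoiseSpec(seed = 3))
  expect_equal(unname(truthMatrix(tr)), unname(couplingMatrix(tr@spec) > 0))
  expect_equal(sum(truthMatrix(tr)), 2)
})

test_that("logistic map fixed point and chaotic range behave classically", {
  spec <- NetworkSpec(matrix(0, 1, 1), "LM",
                      list(r = 2, x0 = 0.5))
  tr <- simulateLogisticMap(spec, 20, NoiseSpec(seed = 1), burnIn = 5)
  expect_equal(tsValues(trialSeries(tr))[, 1], rep(0.5, 20))

  chaotic <- NetworkSpec(matrix(0, 1, 1), "LM", list(r = 3.9))
  x <- tsValues(trialSeries(simulateLogisticMap(chaotic, 500,
                                                NoiseSpec(seed = 2))))[, 1]
  expect_true(all(x > 0 & x < 1))
  # largest Lyapunov exponent of r x (1 - x): mean log |r (1 - 2x)| > 0
  expect_gt(mean(log(abs(3.9 * (1 - 2 * x)))), 0)
})

test_that("uncoupled Van der Pol settles on its limit cycle", {
  tr <- simulateVDP(makeTopologies("two_var", K = c(0, 0),
                                   system = "VDP")[[1]],
                    300, NoiseSpec(seed = 3))
  v <- tsValues(trialSeries(tr))
  expect_equal(unname(apply(abs(v), 2, max)), c(2, 2), tolerance = 0.05)
})

test_that("strong symmetric coupling synchronizes the oscillators", {
  tr <- makeFixture("vdp-synchronous", seed = 5, L = 300)
  v <- tsValues(trialSeries(tr))
  expect_gt(abs(cor(v[, 1], v[, 2])), 0.98)
})

test_that("AR(1) reproduces its autocorrelation; instability is refused", {
  spec <- NetworkSpec(matrix(0, 1, 1), "AR", list(a = list(0.9)))
  x <- tsValues(trialSeries(simulateAR(spec, 3000,
                                       NoiseSpec(dynEps = 1,
                                                 seed = 2))))[, 1]
  expect_equal(acf(x, plot = FALSE)$acf[2], 0.9, tolerance = 0.05)

  unstable <- NetworkSpec(matrix(c(0, 0.6, 0.6, 0), 2, 2), "AR",
                          list(a = list(0.9, 0.9)))
  expect_error(simulateAR(unstable, 100), "unstable")
})

test_that("coupled AR cross-correlation grows with K", {
  xcorAt <- function(K) {
    spec <- makeTopologies("two_var", K = c(K, 0), system = "AR")[[1]]
    spec@systemParams <- list(a = list(0.5, 0.5))
    v <- tsValues(trialSeries(simulateAR(spec, 3000,
                                         NoiseSpec(dynEps = 1, seed = 7))))
    cor(v[-nrow(v), 1], v[-1, 2])  # x(t) vs y(t+1)
  }
  cc <- c(xcorAt(0), xcorAt(0.2), xcorAt(0.5))
  expect_true(all(diff(cc) > 0))
  expect_lt(abs(cc[1]), 0.06)
})

test_that("measurement noise hits the requested SNR", {
  tr <- simulateVDP(makeTopologies("two_var", K = c(0, 0),
                                   system = "VDP")[[1]],
                    2000, NoiseSpec(seed = 11))
  clean <- trialSeries(tr)
  expect_identical(addMeasurementNoise(clean, Inf), clean)
  for (snr in c(0, 20)) {
    noisy <- addMeasurementNoise(clean, snr, seed = 5)
    resid <- tsValues(noisy)[, 1] - tsValues(clean)[, 1]
    sig <- tsValues(clean)[, 1]
    snrHat <- 20 * log10(sd(sig) / sd(resid))
    expect_equal(snrHat, snr, tolerance = 1)
  }
  flat <- TimeSeries(cbind(a = rep(1, 50), b = rnorm(50)))
  expect_error(addMeasurementNoise(flat, 20, seed = 1), "zero variance")
})

test_that("identical specs and seeds reproduce trials bit for bit", {
  spec <- makeTopologies("three_var", K = 0.1)[[2]]
  a <- simulateLogisticMap(spec, 100, NoiseSpec(dynEps = 0.01, seed = 42))
  b <- simulateLogisticMap(spec, 100, NoiseSpec(dynEps = 0.01, seed = 42))
  expect_identical(tsValues(trialSeries(a)), tsValues(trialSeries(b)))

  v1 <- simulateVDP(makeTopologies("two_var", K = c(0.1, 0),
                                   system = "VDP")[[1]], 50,
                    NoiseSpec(dynEps = 0.2, seed = 7))
  v2 <- simulateVDP(makeTopologies("two_var", K = c(0.1, 0),
                                   system = "VDP")[[1]], 50,
                    NoiseSpec(dynEps = 0.2, seed = 7))
  expect_identical(tsValues(trialSeries(v1)), tsValues(trialSeries(v2)))
})

test_that("noise controls are orthogonal: zero noise is deterministic", {
  spec <- makeTopologies("two_var", K = c(0.2, 0))[[1]]
  a <- simulateLogisticMap(spec, 80, NoiseSpec(snrDb = Inf, dynEps = 0,
                                               seed = 9))
  b <- simulateLogisticMap(spec, 80, NoiseSpec(snrDb = Inf, dynEps = 0,
                                               seed = 9))
  expect_identical(tsValues(trialSeries(a)), tsValues(trialSeries(b)))
  # same seed with dynamical noise must differ from the deterministic path
  c <- simulateLogisticMap(spec, 80, NoiseSpec(dynEps = 0.02, seed = 9))
  expect_false(identical(tsValues(trialSeries(a)), tsValues(trialSeries(c))))
})

test_that("uncoupled channels with independent seeds are uncorrelated", {
  cors <- sapply(1:60, function(i) {
    tr <- simulateLogisticMap(makeTopologies("two_var", K = c(0, 0))[[1]],
                              200, NoiseSpec(seed = 90000 + 17 * i))
    v <- tsValues(trialSeries(tr))
    cor(v[, 1], v[, 2])
  })
  ci <- t.test(cors)$conf.int
  expect_true(ci[1] < 0 && ci[2] > 0)
})
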
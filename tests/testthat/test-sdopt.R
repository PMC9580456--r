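test_that("the flatness objective is small for a calibrated pure null", {
  set.seed(31)
  u <- rnorm(1e4)
  h <- histogramFlatness(u, sigma = 1)
  expect_equal(h$nSelected, 0)
  expect_equal(h$nBinsUsed, 100L)       # nothing selected -> all bins
  expect_lt(h$sigmaH / (length(u) / 100), 0.25)
})

test_that("the mixture objective prefers the true null SD over the naive", {
  mix <- simulateGaussianOutliers(seed = 32)
  h1 <- histogramFlatness(mix$values, sigma = 1)
  h175 <- histogramFlatness(mix$values, sigma = 1.75)
  expect_lt(h1$sigmaH, h175$sigmaH)
})

test_that("degenerate candidates are inadmissible, not minimal", {
  mix <- simulateGaussianOutliers(seed = 33)
  # sigma -> 0 flags (nearly) everything
  h <- histogramFlatness(mix$values, sigma = 1e-4)
  expect_equal(h$sigmaH, Inf)
  expect_error(histogramFlatness(mix$values, 1, nBins = 1), "nBins")
  expect_error(histogramFlatness(rnorm(50), 1), "at least nBins")
})

test_that("optimizeSD recovers the null SD of the outlier mixture", {
  mix <- simulateGaussianOutliers(seed = 34)
  opt <- optimizeSD(mix$values)
  expect_lt(abs(sigmaOpt(opt) - 1), abs(sigmaOpt(opt) - sigmaNaive(opt)))
  # dominance of the optimum over the naive SD
  expect_lte(histogramFlatness(mix$values, sigmaOpt(opt))$sigmaH,
             histogramFlatness(mix$values, sigmaNaive(opt))$sigmaH)
  expect_true(all(diff(objectiveCurve(opt)$sigma) > 0))
  expect_equal(sigmaRecomputed(opt),
               recomputeSD(mix$values, sigmaOpt(opt)))
})

test_that("optimizeSD recovers a pure Gaussian SD within 15%", {
  set.seed(35)
  u <- rnorm(5000, sd = 2)
  opt <- optimizeSD(u)
  expect_lt(abs(sigmaOpt(opt) - 2) / 2, 0.15)
})

test_that("optimizeSD is scale-equivariant", {
  mix <- simulateGaussianOutliers(seed = 36)
  s1 <- sigmaOpt(optimizeSD(mix$values))
  s3 <- sigmaOpt(optimizeSD(3 * mix$values))
  expect_equal(s3 / 3, s1, tolerance = 0.05)
})

test_that("optimizeSD rejects degenerate input and empty grids", {
  expect_error(optimizeSD(rep(1, 200)), "constant")
  mix <- simulateGaussianOutliers(seed = 37)
  expect_error(optimizeSD(mix$values, gridRange = c(1e-6, 2e-6)),
               "admissible")
})

test_that("objective dominance holds across random mixtures", {
  for (s in 1:5) {
    set.seed(40 + s)
    u <- c(rnorm(800, sd = runif(1, 0.5, 3)),
           rep(runif(1, 4, 8), sample(50:150, 1)))
    opt <- optimizeSD(u)
    expect_lte(histogramFlatness(u, sigmaOpt(opt))$sigmaH,
               histogramFlatness(u, sigmaNaive(opt))$sigmaH)
  }
})

test_that("recomputeSD isolates the unselected block", {
  # nothing selected: restriction is the whole set
  set.seed(51)
  u <- rnorm(500)
  expect_identical(recomputeSD(u, sigma = 5, p0 = 0.01), naiveSD(u))
  # +-1 null block plus +-10 outlier block: exactly the outliers selected
  u2 <- c(rep(c(1, -1), each = 500), rep(c(10, -10), each = 50))
  expect_equal(recomputeSD(u2, sigma = 1.5, p0 = 0.01), 1)
  expect_error(recomputeSD(u2, sigma = 0.01, p0 = 0.99), "unselected")
})
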
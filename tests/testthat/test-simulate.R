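test_that("the Gaussian-plus-outliers generator honors its contract", {
  mix <- simulateGaussianOutliers(seed = 7)
  expect_length(mix$values, 1100)
  expect_equal(sum(mix$values == 5), 100)
  expect_equal(sum(mix$isOutlier), 100)
  expect_identical(mix$values, simulateGaussianOutliers(seed = 7)$values)
  expect_false(identical(mix$values,
                         simulateGaussianOutliers(seed = 8)$values))
  # pure null: naive SD ~ 1
  pure <- simulateGaussianOutliers(nOut = 0, seed = 7)
  expect_equal(naiveSD(pure$values), 1, tolerance = 0.05)
  expect_error(simulateGaussianOutliers(nNull = 0, nOut = 0), ">= 2")
})

test_that("two-class counts have the promised shape and labels", {
  sim <- simulateTwoClassCounts(nGenes = 300, nPerClass = 5,
                                degFraction = 0.2, seed = 3)
  expect_equal(dim(sim$matrix), c(300L, 10L))
  expect_equal(sum(sim$classLabels), 5)
  expect_equal(sum(sim$isDeg), 60)
  expect_true(all(sim$lfc[!sim$isDeg] == 0))
  expect_true(all(sim$lfc[sim$isDeg] != 0))
  expect_true(all(sim$matrix >= 0))
  expect_true(all(sim$matrix == round(sim$matrix)))
  expect_identical(sim$matrix,
                   simulateTwoClassCounts(nGenes = 300, nPerClass = 5,
                                          degFraction = 0.2, seed = 3)$matrix)
  expect_error(simulateTwoClassCounts(degFraction = 2), "degFraction")
})

test_that("two-class marginal means match the generative model", {
  sim <- simulateTwoClassCounts(nGenes = 300, nPerClass = 1000,
                                degFraction = 0.3, lfcScale = 1.5,
                                seed = 4)
  mA <- rowMeans(sim$matrix[, sim$classLabels])
  mB <- rowMeans(sim$matrix[, !sim$classLabels])
  expA <- sim$baseline
  expB <- sim$baseline * 2^sim$lfc
  expect_lt(median(abs(mA - expA) / expA), 0.05)
  expect_lt(median(abs(mB - expB) / expB), 0.05)
})

test_that("the negative-binomial option adds extra-Poisson spread", {
  pois <- simulateTwoClassCounts(nGenes = 200, nPerClass = 50, seed = 5)
  nb <- simulateTwoClassCounts(nGenes = 200, nPerClass = 50,
                               dispersion = 0.5, seed = 5)
  vp <- apply(pois$matrix[, pois$classLabels], 1, var)
  vn <- apply(nb$matrix[, nb$classLabels], 1, var)
  expect_gt(median(vn / vp), 2)
})

test_that("planted tensors carry the signal where declared", {
  pt <- simulatePlantedTensor(nGenes = 200, nSamples = 6, nConditions = 3,
                              signalGenes = 20, signalCondition = 2,
                              effect = 4, seed = 6)
  expect_equal(dim(pt$tensor), c(200L, 6L, 3L))
  expect_equal(sum(pt$isSignal), 20)
  d <- rowMeans(pt$tensor[, pt$contrast > 0, 2]) -
    rowMeans(pt$tensor[, pt$contrast < 0, 2])
  expect_gt(mean(d[pt$isSignal]), 3)
  expect_lt(abs(mean(d[!pt$isSignal])), 0.5)
  expect_error(simulatePlantedTensor(nGenes = 10, signalGenes = 20),
               "signalGenes")
  expect_error(simulatePlantedTensor(nSamples = 5), "even")
})

test_that("a null tensor shows no component specially aligned with the contrast", {
  pt <- simulatePlantedTensor(nGenes = 400, nSamples = 10, effect = 0,
                              seed = 8)
  td <- hosvd(standardizeTensor(pt$tensor))
  u2 <- factorMatrix(td, 2)
  stat <- max(abs(cor(u2, pt$contrast)))
  set.seed(80)
  permStats <- replicate(50, max(abs(cor(u2, sample(pt$contrast)))))
  expect_lt(stat, max(permStats) * 1.25)
})

test_that("the uniform MA demonstration reproduces its geometry", {
  d <- simulateUniformMA(1e5, deltaThreshold = 0.5, seed = 9)
  # two corner triangles of the unit square: area 1/4
  expect_equal(mean(d$flagged), 0.25, tolerance = 0.01)
  expect_equal(sum(simulateUniformMA(1000, deltaThreshold = 1,
                                     seed = 9)$flagged), 0)
  # Delta = y (2^LFC - 1) is an algebraic identity of the MA coordinates
  expect_equal(d$delta, d$y * (2^d$M - 1), tolerance = 1e-12)
})
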
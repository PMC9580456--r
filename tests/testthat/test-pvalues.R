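test_that("chi-squared P-values match closed-form reference points", {
  expect_equal(chi2Pvalues(0, 1), 1)
  # |u| = sigma: two-sided Gaussian tail 2(1 - Phi(1))
  expect_equal(chi2Pvalues(1.75, 1.75), 2 * (1 - pnorm(1)),
               tolerance = 1e-10)
  expect_equal(chi2Pvalues(1, 1), 0.31731, tolerance = 1e-5)
  # the mixture-outlier regime: (5/1.75)^2 ~ 8.16
  expect_equal(chi2Pvalues(5, 1.75), 0.00427, tolerance = 1e-2)
})

test_that("chi-squared P-values are two-sided and sigma-monotone", {
  set.seed(21)
  u <- rnorm(50)
  expect_identical(chi2Pvalues(u, 1.3), chi2Pvalues(-u, 1.3))
  p1 <- chi2Pvalues(u, 0.8)
  p2 <- chi2Pvalues(u, 1.6)
  expect_true(all(p2 >= p1))
  # strictly decreasing in |u|
  p <- chi2Pvalues(c(0.1, 0.5, 2, 4), 1)
  expect_true(all(diff(p) < 0))
  expect_error(chi2Pvalues(u, 0), "positive")
  expect_error(chi2Pvalues(u, -1), "positive")
  # clamped, never exactly zero
  expect_gt(chi2Pvalues(1e5, 1e-3), 0)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhAdjust(0.37), 0.37)
  # exhaustive on the 0.1k grid up to length 3
  grid <- seq(0.1, 1, by = 0.1)
  for (n in 1:3) {
    combos <- as.matrix(expand.grid(rep(list(grid), n)))
    for (r in seq_len(nrow(combos))) {
      p <- unname(combos[r, ])
      expect_equal(bhAdjust(p), bruteBH(p))
    }
  }
  # random grid vectors up to length 8
  set.seed(22)
  for (rep in 1:200) {
    p <- sample(grid, sample(4:8, 1), replace = TRUE)
    expect_equal(bhAdjust(p), bruteBH(p))
  }
  expect_error(bhAdjust(numeric(0)), "empty")
  expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("naive SD is the population SD with divisor N", {
  expect_equal(naiveSD(c(-1, 1)), 1)
  expect_equal(naiveSD(c(0, 0, 3, 3)), 1.5)
  expect_error(naiveSD(rep(2, 10)), "constant")
  expect_error(naiveSD(3), "at least 2")
})

test_that("the pooled SD of the outlier mixture is ~1.75 as reported", {
  sds <- vapply(1:20, function(s) {
    naiveSD(simulateGaussianOutliers(seed = s)$values)
  }, numeric(1))
  expect_gt(mean(sds), 1.70)
  expect_lt(mean(sds), 1.80)
})

test_that("selection flags follow the adjusted-P threshold", {
  sel <- selectFeatures(c(0.0001, 0.04), threshold = 0.01)
  expect_equal(isSelected(sel), c(TRUE, FALSE))
  expect_true(all(adjustedP(sel) >= rawP(sel)))

  set.seed(23)
  p <- runif(200)^2
  counts <- vapply(c(0.2, 0.1, 0.05, 0.01),
                   function(th) sum(isSelected(selectFeatures(p, th))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("P-values are calibrated under a matched Gaussian null", {
  set.seed(24)
  u <- rnorm(1e4, sd = 2.5)
  p <- chi2Pvalues(u, 2.5)
  ks <- suppressWarnings(ks.test(p, "punif"))
  # 1% critical value for the KS statistic at n = 1e4
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1e4))
})

test_that("attributePvalues composes scoring and selection", {
  u <- c(rnorm(500), 8)
  sel <- attributePvalues(u, sigma = 1)
  expect_s4_class(sel, "FESelection")
  expect_equal(nullSD(sel), 1)
  expect_true(isSelected(sel)[501])
  expect_equal(rawP(sel), chi2Pvalues(u, 1))
})
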
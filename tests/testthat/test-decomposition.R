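test_that("PCA matches the dense gram-matrix eigendecomposition", {
  set.seed(11)
  for (dims in list(c(6, 4), c(12, 5), c(20, 20), c(5, 9))) {
    x <- randomStandardized(dims[1], dims[2])
    d <- pcaDecompose(x)
    o <- gramPCA(x)
    expect_equal(eigenValues(d), o$values, tolerance = 1e-8)
    expect_lt(max(abs(pcScores(d) - matchSign(pcScores(d), o$vectors))),
              1e-8)
  }
})

test_that("PCA satisfies the loading and trace identities", {
  set.seed(12)
  x <- randomStandardized(30, 6)
  d <- pcaDecompose(x)
  # v_lj = sum_i x_ij u_li
  expect_equal(pcLoadings(d), t(x) %*% pcScores(d),
               tolerance = 1e-10, ignore_attr = TRUE)
  # loading orthogonality: v_l . v_l' = lambda_l delta_ll'
  vtv <- crossprod(pcLoadings(d))
  expect_equal(vtv, diag(eigenValues(d)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # trace conservation for standardized input
  expect_equal(sum(eigenValues(d)), 30 * 6, tolerance = 1e-8)
  expect_equal(sum(contributions(d)), 1)
  # orthonormal scores
  expect_equal(crossprod(pcScores(d)), diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a rank-1 matrix has a single nonzero eigenvalue", {
  a <- outer(c(1, -2, 3, 0.5), c(2, 1, -1))
  d <- pcaDecompose(a)
  expect_equal(contributions(d)[1], 1, tolerance = 1e-12)
  expect_lt(eigenValues(d)[2], 1e-8)
})

test_that("the sign convention makes PCA deterministic", {
  set.seed(13)
  x <- randomStandardized(15, 4)
  d1 <- pcaDecompose(x)
  d2 <- pcaDecompose(x)
  expect_identical(pcScores(d1), pcScores(d2))
  for (l in 1:4) {
    i <- which.max(abs(pcScores(d1)[, l]))
    expect_gt(pcScores(d1)[i, l], 0)
  }
})

test_that("HOSVD factors match the unfolding-SVD oracle and reconstruct", {
  set.seed(14)
  x <- array(rnorm(27), c(3, 3, 3))
  td <- hosvd(x)
  for (n in 1:3) {
    u <- factorMatrix(td, n)
    o <- oracleUnfoldingSVD(x, n)[, seq_len(ncol(u)), drop = FALSE]
    expect_lt(max(abs(u - matchSign(u, o))), 1e-8)
  }
  expect_lt(max(abs(reconstructTensor(td) - x)) / max(abs(x)), 1e-8)

  y <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  tdy <- hosvd(y)
  expect_lt(sqrt(sum((reconstructTensor(tdy) - y)^2) / sum(y^2)), 1e-8)
})

test_that("a rank-1 tensor yields a single dominant core entry", {
  a <- c(1, 2, -1) / sqrt(6)
  b <- c(3, 4) / 5
  cc <- c(1, 1) / sqrt(2)
  x <- outer(outer(a, b), cc)
  td <- hosvd(x)
  g <- coreTensor(td)
  expect_equal(max(abs(g)), 1, tolerance = 1e-10)
  expect_lt(sort(abs(g), decreasing = TRUE)[2], 1e-10)
})

test_that("core slices are mutually orthogonal (all-orthogonality)", {
  set.seed(15)
  td <- hosvd(array(rnorm(4 * 4 * 3), c(4, 4, 3)))
  g <- coreTensor(td)
  for (n in 1:3) {
    gu <- sigmaFE:::unfoldTensor(g, n)
    gram <- tcrossprod(gu)
    expect_lt(max(abs(gram - diag(diag(gram)))), 1e-8)
  }
})

test_that("truncated HOSVD keeps the requested ranks", {
  set.seed(16)
  td <- hosvd(array(rnorm(10 * 6 * 4), c(10, 6, 4)), ranks = c(3, 2, 2))
  expect_equal(dim(coreTensor(td)), c(3L, 2L, 2L))
})

test_that("axis selection follows correlation then core magnitude", {
  set.seed(17)
  x <- randomStandardized(25, 5)
  d <- pcaDecompose(x)
  # target equal to a loading column: self-correlation 1
  expect_equal(selectAxes(d, targetSample = pcLoadings(d)[, 2])$feature, 2)

  td <- hosvd(standardizeTensor(array(rnorm(30 * 6 * 3), c(30, 6, 3))))
  tgt2 <- factorMatrix(td, 2)[, 3]
  tgt3 <- factorMatrix(td, 3)[, 1]
  # plant a unique core maximum at feature axis 5 of the matched slice
  g <- coreTensor(td)
  g[5, 3, 1] <- 2 * max(abs(g)) + 1
  tdMod <- methods::new("TensorDecomposition", factors = td@factors,
                        core = g)
  sel <- selectAxes(tdMod, targetSample = tgt2, targetCondition = tgt3)
  expect_equal(sel$feature, 5L)
  expect_equal(sel$sample, 3L)
  expect_equal(sel$condition, 1L)
})

test_that("core-magnitude ties resolve to the smallest feature index", {
  f <- list(diag(4), diag(3), diag(2))
  g <- array(0, c(4, 3, 2))
  g[2, 1, 1] <- 1
  g[4, 1, 1] <- -1  # tie in |G|
  td <- methods::new("TensorDecomposition", factors = f, core = g)
  sel <- selectAxes(td, targetSample = c(5, 0, 0),
                    targetCondition = c(1, -1))
  expect_equal(sel$feature, 2L)
})

test_that("axis selection validates its inputs", {
  set.seed(18)
  d <- pcaDecompose(randomStandardized(10, 4))
  expect_error(selectAxes(d, targetSample = rep(1, 4)), "zero variance")
  expect_error(selectAxes(d, targetSample = c(1, -1)), "length")
  expect_error(selectAxes(d, mode = "explicit", explicitIndices = 9),
               "out of range")
  expect_equal(selectAxes(d, mode = "explicit", explicitIndices = 3)$feature,
               3L)
})
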
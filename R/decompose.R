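#' Principal-component decomposition of an expression matrix
#'
#' Computes the feature-side PC scores \eqn{u_{\ell i}}, sample-side
#' loadings \eqn{v_{\ell j} = \sum_i x_{ij} u_{\ell i}}, and gram-matrix
#' eigenvalues \eqn{\lambda_\ell} of a (standardized) feature-by-sample
#' matrix.  The scores and eigenvalues are mathematically identical to the
#' eigendecomposition of the N x N feature gram matrix
#' \eqn{\sum_j x_{ij} x_{i'j}}, but are obtained through the thin SVD of
#' \code{x} so the N x N matrix is never materialized (N can be large).
#'
#' Each score column's sign is fixed so that its largest-magnitude entry is
#' positive, with the same sign propagated to the paired loading column;
#' downstream P-values only use squared scores, so this is purely a
#' reproducibility convention.
#'
#' @param x numeric feature-by-sample matrix (typically the output of
#'   [standardizeMatrix()]), or a \code{SummarizedExperiment}.
#'
#' @return a [MatrixDecomposition-class] object with
#'   \code{L = min(N, M)} components.
#'
#' @examples
#' x <- standardizeMatrix(matrix(rpois(60, 20), 10, 6))
#' d <- pcaDecompose(x)
#' sum(eigenValues(d))  # == 10 * 6 for standardized input
#' @export
pcaDecompose <- function(x) {
  x <- asExpressionMatrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("need at least 2 features and 2 samples", call. = FALSE)
  }
  assertFinite(x, "input matrix")
  s <- svd(x)
  scores <- s$u
  loadings <- s$v %*% diag(s$d, length(s$d))
  # deterministic sign convention
  for (l in seq_along(s$d)) {
    i <- which.max(abs(scores[, l]))
    if (scores[i, l] < 0) {
      scores[, l] <- -scores[, l]
      loadings[, l] <- -loadings[, l]
    }
  }
  ev <- s$d^2
  cn <- paste0("PC", seq_along(ev))
  dimnames(scores) <- list(rownames(x), cn)
  dimnames(loadings) <- list(colnames(x), cn)
  methods::new("MatrixDecomposition",
    scores = scores, loadings = loadings, eigenvalues = ev,
    contributions = ev / sum(ev))
}

## ---- tensor algebra ----

# mode-n unfolding of a 3-mode array into a matrix (mode dim x rest)
unfoldTensor <- function(x, mode) {
  d <- dim(x)
  stopifnot(length(d) == 3, mode %in% 1:3)
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(x, perm), nrow = d[mode])
}

# mode-n product: contract array x with matrix m along mode n
ttm <- function(x, m, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(1:3, mode))
  y <- m %*% unfoldTensor(x, mode)
  newd <- c(nrow(m), d[setdiff(1:3, mode)])
  aperm(array(y, newd), order(perm))
}

#' Higher-order singular value decomposition (HOSVD)
#'
#' Tucker decomposition of a 3-mode tensor in which each factor matrix holds
#' the left singular vectors of the corresponding mode unfolding, and the
#' core is the tensor contracted with the factor transposes.  With full
#' unfolding ranks (the default) the decomposition is exact:
#' \code{reconstructTensor(hosvd(x))} reproduces \code{x} to numerical
#' precision.
#'
#' The same sign convention as [pcaDecompose()] is applied to every factor
#' column (largest-magnitude entry positive) before the core is formed, so
#' repeated runs are bit-identical.
#'
#' @param x numeric 3-mode array (features x samples x conditions), finite.
#'   Standardization (see [standardizeTensor()]) is the caller's job.
#' @param ranks optional integer vector of length 3: number of factor
#'   columns retained per mode (truncated HOSVD).  Default keeps the full
#'   unfolding ranks.
#'
#' @return a [TensorDecomposition-class] object.
#'
#' @examples
#' a <- array(rnorm(24), c(4, 3, 2))
#' td <- hosvd(a)
#' max(abs(reconstructTensor(td) - a))  # ~1e-15
#' @export
hosvd <- function(x, ranks = NULL) {
  d <- dim(x)
  if (length(d) != 3 || any(d < 1)) {
    stop("x must be a 3-mode array with positive extents", call. = FALSE)
  }
  assertFinite(x, "input tensor")
  dn <- dimnames(x)
  factors <- vector("list", 3)
  for (n in 1:3) {
    un <- unfoldTensor(x, n)
    full <- min(nrow(un), ncol(un))
    r <- if (is.null(ranks)) full else min(ranks[n], full)
    u <- svd(un, nu = r, nv = 0)$u
    for (l in seq_len(ncol(u))) {
      i <- which.max(abs(u[, l]))
      if (u[i, l] < 0) u[, l] <- -u[, l]
    }
    rownames(u) <- if (!is.null(dn)) dn[[n]] else NULL
    colnames(u) <- paste0("L", seq_len(ncol(u)))
    factors[[n]] <- u
  }
  core <- x
  for (n in 1:3) core <- ttm(core, t(factors[[n]]), n)
  methods::new("TensorDecomposition", factors = factors, core = core)
}

#' Reconstruct a tensor from its Tucker factors
#'
#' Contracts the core with the three factor matrices
#' (\eqn{x_{ijk} = \sum G(\ell_1 \ell_2 \ell_3)
#' u_{\ell_1 i} u_{\ell_2 j} u_{\ell_3 k}}).
#'
#' @param decomposition a [TensorDecomposition-class] object.
#' @return a numeric 3-mode array.
#' @export
reconstructTensor <- function(decomposition) {
  stopifnot(methods::is(decomposition, "TensorDecomposition"))
  x <- decomposition@core
  for (n in 1:3) x <- ttm(x, decomposition@factors[[n]], n)
  x
}

#' Select the decomposition axes matching a target contrast
#'
#' Identifies the component(s) of a decomposition associated with a desired
#' sample property (e.g. the control/treated contrast).  In
#' \code{"correlation"} mode the sample axis is the loading / factor column
#' with the largest absolute Pearson correlation to \code{targetSample}
#' (and, for tensors, the condition axis likewise against
#' \code{targetCondition}); the feature axis of a tensor decomposition is
#' then the \eqn{\ell_1} maximizing \eqn{|G(\ell_1, \ell_2, \ell_3)|} over
#' the matched \eqn{(\ell_2, \ell_3)}.  When no condition target is given,
#' \eqn{(\ell_1, \ell_3)} jointly maximize \eqn{|G|} over the matched
#' \eqn{\ell_2} slice.  Ties in \eqn{|G|} resolve to the smallest index.
#'
#' @param decomposition a [MatrixDecomposition-class] or
#'   [TensorDecomposition-class] object.
#' @param targetSample numeric vector over samples (required in
#'   \code{"correlation"} mode); must have nonzero variance.
#' @param targetCondition optional numeric vector over conditions (tensor
#'   only).
#' @param mode \code{"correlation"} (default) or \code{"explicit"}.
#' @param explicitIndices in \code{"explicit"} mode: the component index
#'   \eqn{\ell} (matrix) or \code{c(l1, l2, l3)} (tensor); bounds-checked.
#'
#' @return a list with elements \code{feature}, \code{sample} and (tensor
#'   only) \code{condition}: the selected component indices.  For a matrix
#'   decomposition \code{feature == sample} (scores and loadings are
#'   paired).
#'
#' @examples
#' x <- standardizeMatrix(matrix(rnorm(40), 10, 4))
#' d <- pcaDecompose(x)
#' selectAxes(d, targetSample = pcLoadings(d)[, 2])$feature  # 2
#' @export
selectAxes <- function(decomposition, targetSample = NULL,
                       targetCondition = NULL,
                       mode = c("correlation", "explicit"),
                       explicitIndices = NULL) {
  mode <- match.arg(mode)
  isTensor <- methods::is(decomposition, "TensorDecomposition")
  if (!isTensor && !methods::is(decomposition, "MatrixDecomposition")) {
    stop("decomposition must be a MatrixDecomposition or TensorDecomposition",
         call. = FALSE)
  }

  if (mode == "explicit") {
    if (is.null(explicitIndices)) {
      stop("explicit mode requires explicitIndices", call. = FALSE)
    }
    if (!isTensor) {
      l <- as.integer(explicitIndices[1])
      if (l < 1 || l > length(decomposition@eigenvalues)) {
        stop("component index ", l, " out of range", call. = FALSE)
      }
      return(list(feature = l, sample = l))
    }
    if (length(explicitIndices) != 3) {
      stop("tensor explicit mode requires c(l1, l2, l3)", call. = FALSE)
    }
    li <- as.integer(explicitIndices)
    ranks <- dim(decomposition@core)
    if (any(li < 1) || any(li > ranks)) {
      stop("explicit indices out of range for core of dimension ",
           paste(ranks, collapse = " x "), call. = FALSE)
    }
    return(list(feature = li[1], sample = li[2], condition = li[3]))
  }

  absCorWith <- function(mat, target, what) {
    if (length(target) != nrow(mat)) {
      stop(what, " target length (", length(target),
           ") does not match the mode length (", nrow(mat), ")",
           call. = FALSE)
    }
    if (stats::sd(target) == 0) {
      stop(what, " target has zero variance", call. = FALSE)
    }
    sds <- apply(mat, 2, stats::sd)
    cc <- rep(0, ncol(mat))
    ok <- sds > 0
    cc[ok] <- abs(stats::cor(mat[, ok, drop = FALSE], target))
    cc
  }

  if (!isTensor) {
    if (is.null(targetSample)) {
      stop("correlation mode requires targetSample", call. = FALSE)
    }
    cc <- absCorWith(decomposition@loadings, targetSample, "sample")
    l <- which.max(cc)
    return(list(feature = l, sample = l, correlation = cc[l]))
  }

  if (is.null(targetSample)) {
    stop("correlation mode requires targetSample", call. = FALSE)
  }
  cc2 <- absCorWith(decomposition@factors[[2]], targetSample, "sample")
  l2 <- which.max(cc2)
  G <- decomposition@core
  if (!is.null(targetCondition)) {
    cc3 <- absCorWith(decomposition@factors[[3]], targetCondition,
                      "condition")
    l3 <- which.max(cc3)
    g <- abs(G[, l2, l3])
    l1 <- which.max(g)          # ties -> smallest index
  } else {
    g <- abs(G[, l2, , drop = FALSE])
    idx <- which(g == max(g), arr.ind = TRUE)
    # smallest feature index first, then smallest condition index
    idx <- idx[order(idx[, 1], idx[, 3]), , drop = FALSE]
    l1 <- idx[1, 1]
    l3 <- idx[1, 3]
  }
  list(feature = as.integer(l1), sample = as.integer(l2),
       condition = as.integer(l3))
}
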
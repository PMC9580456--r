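#' @import methods
NULL

#' Matrix decomposition of a standardized expression matrix
#'
#' Holds the thin singular value decomposition of a feature-by-sample
#' expression matrix in the parameterization used for unsupervised feature
#' extraction: feature-side principal-component scores \eqn{u_{\ell i}}
#' (orthonormal columns), sample-side loadings \eqn{v_{\ell j}} with
#' \eqn{\|v_\ell\|^2 = \lambda_\ell}, the eigenvalues \eqn{\lambda_\ell}
#' of the gram matrix, and their relative contributions.
#'
#' @slot scores numeric matrix, N features x L components; orthonormal columns.
#' @slot loadings numeric matrix, M samples x L components;
#'   \code{loadings[, l]} equals the projection of each sample onto score
#'   column \code{l}, so its squared norm is \code{eigenvalues[l]}.
#' @slot eigenvalues numeric vector of length L, nonincreasing, nonnegative.
#' @slot contributions numeric vector of length L summing to 1.
#'
#' @seealso [pcaDecompose()], [pcScores()], [pcLoadings()]
#' @export
setClass("MatrixDecomposition",
  representation(
    scores = "matrix",
    loadings = "matrix",
    eigenvalues = "numeric",
    contributions = "numeric"
  )
)

setValidity("MatrixDecomposition", function(object) {
  msg <- character()
  L <- length(object@eigenvalues)
  if (ncol(object@scores) != L) {
    msg <- c(msg, "ncol(scores) must equal length(eigenvalues)")
  }
  if (ncol(object@loadings) != L) {
    msg <- c(msg, "ncol(loadings) must equal length(eigenvalues)")
  }
  if (length(object@contributions) != L) {
    msg <- c(msg, "length(contributions) must equal length(eigenvalues)")
  }
  if (any(object@eigenvalues < -1e-8)) {
    msg <- c(msg, "eigenvalues must be nonnegative")
  }
  if (is.unsorted(rev(object@eigenvalues), strict = FALSE)) {
    msg <- c(msg, "eigenvalues must be nonincreasing")
  }
  if (L > 0 && abs(sum(object@contributions) - 1) > 1e-6) {
    msg <- c(msg, "contributions must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Tucker/HOSVD decomposition of a three-mode expression tensor
#'
#' The higher-order SVD of a feature x sample x condition array: one
#' orthonormal factor matrix per mode (columns are the left singular vectors
#' of the corresponding mode unfolding) and the all-orthogonal core array
#' obtained by contracting the tensor with the factor transposes.
#'
#' @slot factors list of three numeric matrices (feature, sample, condition
#'   mode), each with orthonormal columns.
#' @slot core numeric 3-mode array with dimensions matching the factor ranks.
#'
#' @seealso [hosvd()], [factorMatrix()], [coreTensor()], [reconstructTensor()]
#' @export
setClass("TensorDecomposition",
  representation(
    factors = "list",
    core = "array"
  )
)

setValidity("TensorDecomposition", function(object) {
  msg <- character()
  if (length(object@factors) != 3) {
    msg <- c(msg, "factors must be a list of 3 matrices")
  } else if (!all(vapply(object@factors, is.matrix, logical(1)))) {
    msg <- c(msg, "each factor must be a matrix")
  } else if (length(dim(object@core)) != 3) {
    msg <- c(msg, "core must be a 3-mode array")
  } else {
    ranks <- vapply(object@factors, ncol, integer(1))
    if (!all(dim(object@core) == ranks)) {
      msg <- c(msg, "core dimensions must match factor column counts")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-feature P-value assignment and selection
#'
#' Raw chi-squared P-values for a score vector under a Gaussian null of
#' standard deviation \code{sigma}, their Benjamini-Hochberg adjustment, and
#' the selection flags at an adjusted-P threshold.
#'
#' @slot sigma the null SD used to compute the raw P-values (NA when the raw
#'   P-values were supplied directly).
#' @slot u the score vector (NA-filled when unavailable).
#' @slot rawP raw P-values in (0, 1].
#' @slot adjustedP BH-adjusted P-values.
#' @slot selected logical; \code{adjustedP <= threshold}.
#' @slot threshold the adjusted-P selection cutoff.
#'
#' @seealso [selectFeatures()], [attributePvalues()]
#' @export
setClass("FESelection",
  representation(
    sigma = "numeric",
    u = "numeric",
    rawP = "numeric",
    adjustedP = "numeric",
    selected = "logical",
    threshold = "numeric"
  )
)

setValidity("FESelection", function(object) {
  msg <- character()
  n <- length(object@rawP)
  if (length(object@adjustedP) != n || length(object@selected) != n) {
    msg <- c(msg, "rawP, adjustedP and selected must have equal length")
  }
  if (any(object@rawP <= 0) || any(object@rawP > 1)) {
    msg <- c(msg, "rawP must lie in (0, 1]")
  }
  if (any(object@adjustedP + 1e-12 < object@rawP)) {
    msg <- c(msg, "adjustedP must be >= rawP elementwise")
  }
  if (length(object@threshold) != 1 ||
      object@threshold <= 0 || object@threshold >= 1) {
    msg <- c(msg, "threshold must be a single value in (0, 1)")
  }
  if (n > 0 && !identical(object@selected,
                          object@adjustedP <= object@threshold)) {
    msg <- c(msg, "selected must equal adjustedP <= threshold")
  }
  if (length(msg)) msg else TRUE
})

#' Result of the histogram-flatness SD optimization
#'
#' @slot sigmaNaive pooled (all-feature) population SD of the scores.
#' @slot sigmaOpt the SD minimizing the flatness objective.
#' @slot sigmaRecomputed population SD restricted to features not selected at
#'   \code{sigmaOpt} (the presumed-null part).
#' @slot curve data.frame with columns \code{sigma}, \code{sigmaH},
#'   \code{nSelected}, \code{nBinsUsed}: the objective evaluated on the
#'   search grid (sigma strictly increasing).
#' @slot p0 adjusted-P threshold defining "selected" inside the objective.
#' @slot nBins number of equal-width histogram bins on [0, 1].
#' @slot nSelectedAtOpt number of features selected at \code{sigmaOpt}.
#'
#' @seealso [optimizeSD()], [sigmaOpt()], [objectiveCurve()]
#' @export
setClass("SDOptimization",
  representation(
    sigmaNaive = "numeric",
    sigmaOpt = "numeric",
    sigmaRecomputed = "numeric",
    curve = "data.frame",
    p0 = "numeric",
    nBins = "numeric",
    nSelectedAtOpt = "numeric"
  )
)

setValidity("SDOptimization", function(object) {
  msg <- character()
  if (object@sigmaOpt <= 0) msg <- c(msg, "sigmaOpt must be positive")
  if (object@sigmaNaive <= 0) msg <- c(msg, "sigmaNaive must be positive")
  if (!all(c("sigma", "sigmaH") %in% names(object@curve))) {
    msg <- c(msg, "curve must have columns sigma and sigmaH")
  } else if (is.unsorted(object@curve$sigma, strict = TRUE)) {
    msg <- c(msg, "curve sigmas must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})
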
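#' Standardize an expression matrix sample-wise
#'
#' Centers and scales every sample (column) across features so that
#' \eqn{\sum_i x_{ij} = 0} and \eqn{\sum_i x_{ij}^2 = N} for each sample
#' \eqn{j}, where \eqn{N} is the number of features.  This is the
#' standardization under which the gram-matrix eigenvalues of the
#' decomposition sum to \eqn{N \times M}.
#'
#' @param x numeric feature-by-sample matrix, or a
#'   \code{SummarizedExperiment} (first assay is used).  At least 2 features
#'   and 2 samples; all values finite.
#' @param log2Transform if \code{TRUE}, apply \code{log2(x + pseudocount)}
#'   before standardizing (useful for raw counts).
#' @param pseudocount nonnegative offset used inside the log transform.
#'
#' @return a numeric matrix of the same dimensions (dimnames preserved),
#'   each column with mean 0 and sum of squares \eqn{N}.
#'
#' @details A sample whose values are constant across features (zero
#'   variance after the optional transform) cannot be standardized; the
#'   error message names the offending sample.
#'
#' @examples
#' m <- matrix(c(0, 0, 6, 1, 2, 3), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' s <- standardizeMatrix(m)
#' colSums(s)    # ~0
#' colSums(s^2)  # ~3
#' @export
standardizeMatrix <- function(x, log2Transform = FALSE, pseudocount = 1) {
  x <- asExpressionMatrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("need at least 2 features and 2 samples", call. = FALSE)
  }
  assertFinite(x, "expression matrix")
  if (log2Transform) {
    if (pseudocount < 0) stop("pseudocount must be nonnegative", call. = FALSE)
    if (any(x + pseudocount <= 0)) {
      stop("log transform requires x + pseudocount > 0 everywhere",
           call. = FALSE)
    }
    x <- log2(x + pseudocount)
  }
  n <- nrow(x)
  ctr <- sweep(x, 2, colMeans(x))
  ssq <- colMeans(ctr^2)
  bad <- ssq <= .Machine$double.eps * 100
  if (any(bad)) {
    nm <- colnames(x)[bad]
    if (is.null(nm)) nm <- which(bad)
    stop("sample(s) with zero variance across features: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  sweep(ctr, 2, sqrt(ssq), "/")
}

#' Standardize a three-mode expression tensor feature-wise
#'
#' For every (sample, condition) pair, centers and scales the fiber over
#' features so that \eqn{\sum_i x_{ijk} = 0} and
#' \eqn{\sum_i x_{ijk}^2 = N}.
#'
#' @param x numeric 3-mode array, features x samples x conditions, all
#'   values finite, at least 2 features.
#'
#' @return a numeric array of the same dimensions (dimnames preserved).
#'
#' @details A constant fiber cannot be standardized; the error names the
#'   (sample, condition) pair.
#' @examples
#' a <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
#' s <- standardizeTensor(a)
#' apply(s, c(2, 3), sum)  # ~0
#' @export
standardizeTensor <- function(x) {
  if (length(dim(x)) != 3) {
    stop("x must be a 3-mode array", call. = FALSE)
  }
  if (dim(x)[1] < 2) stop("need at least 2 features", call. = FALSE)
  assertFinite(x, "expression tensor")
  m <- colMeans(x)                      # M x K fiber means
  ctr <- sweep(x, c(2, 3), m)
  ssq <- colMeans(ctr^2)                # M x K
  bad <- which(ssq <= .Machine$double.eps * 100, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    sn <- dimnames(x)[[2]]
    cn <- dimnames(x)[[3]]
    lab <- apply(bad, 1, function(r) {
      paste0("(",
             if (is.null(sn)) r[1] else sn[r[1]], ", ",
             if (is.null(cn)) r[2] else cn[r[2]], ")")
    })
    stop("constant fiber(s) at (sample, condition): ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  sweep(ctr, c(2, 3), sqrt(ssq), "/")
}
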
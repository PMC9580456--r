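#' Chi-squared P-values for feature scores under a Gaussian null
#'
#' Attributes to each feature the P-value
#' \eqn{P_i = P_{\chi^2}[> (u_i/\sigma)^2]}, the survival function of the
#' chi-squared distribution with one degree of freedom -- i.e. the two-sided
#' tail probability of a centered Gaussian with standard deviation
#' \eqn{\sigma}.  P-values are clamped below at the smallest positive normal
#' double so downstream log-scale diagnostics never see exact zeros.
#'
#' @param u numeric vector of feature scores (finite).
#' @param sigma positive null standard deviation.
#' @return numeric vector of P-values in (0, 1], even in \code{|u|},
#'   strictly decreasing in \code{|u|}.
#' @examples
#' chi2Pvalues(c(0, 1, 5), sigma = 1)
#' @export
chi2Pvalues <- function(u, sigma) {
  assertScalarPositive(sigma, "sigma")
  assertFinite(u, "score vector")
  p <- stats::pchisq((u / sigma)^2, df = 1, lower.tail = FALSE)
  pmax(p, .Machine$double.xmin)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (\code{stats::p.adjust} with
#' \code{method = "BH"}), with input validation: all raw P-values must lie
#' in (0, 1] and the vector must be nonempty.
#'
#' @param p numeric vector of raw P-values.
#' @return adjusted P-values in the original order.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0) stop("empty P-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("raw P-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Pooled population standard deviation of a score vector
#'
#' The mean-centered standard deviation with divisor \eqn{N} (not
#' \eqn{N - 1}): \eqn{\sqrt{\frac{1}{N}\sum_i (u_i - \bar u)^2}}.  This is
#' the "naive" null SD computed from all features, outliers included.
#'
#' @param u numeric vector, length >= 2, nonconstant.
#' @return a positive scalar.
#' @examples
#' naiveSD(c(-1, 1))       # 1
#' naiveSD(c(0, 0, 3, 3))  # 1.5
#' @export
naiveSD <- function(u) {
  if (length(u) < 2) stop("need at least 2 values", call. = FALSE)
  assertFinite(u, "score vector")
  s <- sqrt(mean((u - mean(u))^2))
  if (s <= 0) stop("constant vector has no standard deviation", call. = FALSE)
  s
}

#' Select features at an adjusted-P threshold
#'
#' BH-adjusts raw P-values and flags features with adjusted P at or below
#' the threshold.
#'
#' @param rawP numeric vector of raw P-values in (0, 1].
#' @param threshold adjusted-P cutoff in (0, 1); 0.01 by default (0.1 is
#'   the conventional alternative for tensor analyses).
#' @param u optional score vector stored alongside (for reporting).
#' @param sigma optional null SD stored alongside.
#' @return an [FESelection-class] object.
#' @seealso [attributePvalues()] to go from scores straight to a selection.
#' @export
selectFeatures <- function(rawP, threshold = 0.01, u = NULL, sigma = NULL) {
  if (length(threshold) != 1 || threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single value in (0, 1)", call. = FALSE)
  }
  adj <- bhAdjust(rawP)
  if (is.null(u)) u <- rep(NA_real_, length(rawP))
  if (is.null(sigma)) sigma <- NA_real_
  methods::new("FESelection",
    sigma = as.numeric(sigma), u = as.numeric(u),
    rawP = as.numeric(rawP), adjustedP = adj,
    selected = adj <= threshold, threshold = threshold)
}

#' Attribute P-values to scores and select features
#'
#' Convenience wrapper: [chi2Pvalues()] followed by [selectFeatures()].
#'
#' @inheritParams chi2Pvalues
#' @inheritParams selectFeatures
#' @return an [FESelection-class] object.
#' @examples
#' sel <- attributePvalues(c(rnorm(200), 6), sigma = 1)
#' sum(isSelected(sel))
#' @export
attributePvalues <- function(u, sigma, threshold = 0.01) {
  selectFeatures(chi2Pvalues(u, sigma), threshold = threshold,
                 u = u, sigma = sigma)
}
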
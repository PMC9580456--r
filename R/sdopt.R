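#' Histogram-flatness objective for a candidate null SD
#'
#' Evaluates how far the distribution of \eqn{1 - P_i} over the
#' \emph{unselected} features departs from flatness when P-values are
#' computed with null SD \code{sigma}.  The procedure is self-referential in
#' \code{sigma}: raw P-values are recomputed, BH-adjusted, features with
#' adjusted P \eqn{\le} \code{p0} are flagged as outliers, and the histogram
#' of \eqn{1 - P_i} on \code{nBins} equal-width bins spanning [0, 1] is
#' restricted to the bins whose upper edge does not exceed
#' \eqn{t = \min_{selected}(1 - P_i)} (or \eqn{t = 1} when nothing is
#' selected).  The objective is the population SD (divisor = number of
#' included bins) of the included bin counts.
#'
#' Degenerate candidates are reported as \code{Inf} rather than a value:
#' when fewer than half of the features remain unselected, or fewer than 10
#' bins survive the cut, the candidate corresponds to the meaningless
#' "everything flagged" regime that the optimization must exclude
#' (the limiting case being \eqn{\sigma \to 0}).
#'
#' @param u numeric score vector, length >= \code{nBins}.
#' @param sigma positive candidate null SD.
#' @param p0 adjusted-P threshold defining "selected" inside the objective.
#' @param nBins number of histogram bins (>= 2); 100 by default.
#'
#' @return a list: \code{sigmaH} (the objective; \code{Inf} when
#'   inadmissible), \code{nBinsUsed}, \code{nSelected}.
#' @seealso [optimizeSD()]
#' @export
histogramFlatness <- function(u, sigma, p0 = 0.01, nBins = 100) {
  assertScalarPositive(sigma, "sigma")
  if (nBins < 2) stop("nBins must be at least 2", call. = FALSE)
  if (length(u) < nBins) {
    stop("need at least nBins scores (", nBins, ")", call. = FALSE)
  }
  p <- chi2Pvalues(u, sigma)
  adj <- bhAdjust(p)
  sel <- adj <= p0
  nSel <- sum(sel)
  if (length(u) - nSel < length(u) / 2) {
    return(list(sigmaH = Inf, nBinsUsed = 0L, nSelected = nSel))
  }
  tcut <- if (nSel > 0) min(1 - p[sel]) else 1
  # fixed equal-width bins on [0, 1]; 1 - p == 0 falls in the first bin
  idx <- pmin(pmax(ceiling((1 - p) * nBins), 1L), nBins)
  h <- tabulate(idx, nbins = nBins)
  included <- (seq_len(nBins) / nBins) <= tcut
  nb <- sum(included)
  if (nb < 10) {
    return(list(sigmaH = Inf, nBinsUsed = as.integer(nb), nSelected = nSel))
  }
  hi <- h[included]
  list(sigmaH = sqrt(mean((hi - mean(hi))^2)),
       nBinsUsed = as.integer(nb), nSelected = nSel)
}

#' Optimize the Gaussian-null standard deviation
#'
#' Finds the null SD at which the histogram of \eqn{1 - P} over unselected
#' features is flattest (see [histogramFlatness()]), the package's
#' replacement for the pooled "naive" SD, which is inflated by true
#' outliers.  The objective is evaluated on a log-spaced grid of
#' \code{gridLength} points spanning
#' \code{[sigmaNaive / 50, 2 * sigmaNaive]} by default; inadmissible
#' candidates are discarded, and the grid minimum is refined by bounded
#' scalar minimization between its neighboring grid points.
#'
#' The returned object also carries the recomputed SD -- the pooled SD
#' restricted to features \emph{not} selected at the optimum -- which for a
#' well-calibrated fit approaches the SD of the null (Gaussian) part of the
#' score distribution and serves as a diagnostic.
#'
#' @param u numeric score vector (nonconstant, length >= \code{nBins}).
#' @param p0 adjusted-P threshold used inside the objective (default 0.01).
#' @param nBins number of histogram bins (default 100).
#' @param gridLength number of grid points (default 200).
#' @param gridRange optional length-2 numeric: search interval for sigma;
#'   defaults to \code{c(sigmaNaive / 50, 2 * sigmaNaive)}.
#'
#' @return an [SDOptimization-class] object.
#'
#' @examples
#' u <- c(rnorm(1000), rep(5, 100))  # Gaussian null plus outliers
#' opt <- optimizeSD(u)
#' sigmaNaive(opt)  # ~1.72, inflated by the outliers
#' sigmaOpt(opt)    # ~1, the null SD
#' @export
optimizeSD <- function(u, p0 = 0.01, nBins = 100, gridLength = 200,
                       gridRange = NULL) {
  sn <- naiveSD(u)
  if (is.null(gridRange)) gridRange <- c(sn / 50, 2 * sn)
  if (length(gridRange) != 2 || any(gridRange <= 0) ||
      gridRange[1] >= gridRange[2]) {
    stop("gridRange must be two increasing positive values", call. = FALSE)
  }
  grid <- exp(seq(log(gridRange[1]), log(gridRange[2]),
                  length.out = gridLength))
  evals <- lapply(grid, function(s) histogramFlatness(u, s, p0, nBins))
  sigmaH <- vapply(evals, `[[`, numeric(1), "sigmaH")
  nSel <- vapply(evals, `[[`, integer(1), "nSelected")
  nbu <- vapply(evals, `[[`, integer(1), "nBinsUsed")
  if (all(!is.finite(sigmaH))) {
    stop("no admissible sigma on the search grid; widen gridRange or ",
         "increase p0", call. = FALSE)
  }
  i <- which.min(sigmaH)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(gridLength, i + 1L)]
  f <- function(s) {
    v <- histogramFlatness(u, s, p0, nBins)$sigmaH
    if (!is.finite(v)) 1e300 else v
  }
  best <- grid[i]
  bestVal <- sigmaH[i]
  if (lo < hi) {
    ref <- stats::optimize(f, lower = lo, upper = hi)
    if (ref$objective <= bestVal) {
      best <- ref$minimum
      bestVal <- ref$objective
    }
  }
  atOpt <- histogramFlatness(u, best, p0, nBins)
  methods::new("SDOptimization",
    sigmaNaive = sn,
    sigmaOpt = best,
    sigmaRecomputed = recomputeSD(u, best, p0),
    curve = data.frame(sigma = grid, sigmaH = sigmaH,
                       nSelected = nSel, nBinsUsed = nbu),
    p0 = p0, nBins = as.numeric(nBins),
    nSelectedAtOpt = as.numeric(atOpt$nSelected))
}

#' Pooled SD of the unselected (presumed-null) features
#'
#' Recomputes the population SD restricted to features whose BH-adjusted
#' P-value exceeds \code{p0} when P-values are computed with the given
#' \code{sigma}.  After SD optimization this diagnostic is expected to
#' approach the SD of the Gaussian part of the score distribution.
#'
#' @inheritParams histogramFlatness
#' @return a positive scalar.
#' @export
recomputeSD <- function(u, sigma, p0 = 0.01) {
  adj <- bhAdjust(chi2Pvalues(u, sigma))
  keep <- adj > p0
  if (sum(keep) < 2) {
    stop("fewer than 2 unselected features at this (sigma, p0)",
         call. = FALSE)
  }
  naiveSD(u[keep])
}
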
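#' Gaussian null with planted outliers
#'
#' Draws \code{nNull} i.i.d. standard-normal values and appends
#' \code{nOut} copies of \code{outValue} -- the canonical score mixture for
#' exercising null-SD calibration: the pooled SD is inflated by the
#' outliers (about 1.72 at the defaults) while the null part has SD 1.
#'
#' @param nNull number of standard-normal draws (default 1000).
#' @param nOut number of planted outliers (default 100).
#' @param outValue the constant outlier value (default 5).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#'
#' @return a list: \code{values} (length \code{nNull + nOut}),
#'   \code{isOutlier} (logical labels), \code{nNull}, \code{nOut},
#'   \code{outValue}, \code{seed}.
#' @examples
#' mix <- simulateGaussianOutliers(seed = 1)
#' naiveSD(mix$values)
#' @export
simulateGaussianOutliers <- function(nNull = 1000, nOut = 100, outValue = 5,
                                     seed = 1) {
  if (nNull < 0 || nOut < 0 || nNull + nOut < 2) {
    stop("need nNull + nOut >= 2 nonnegative counts", call. = FALSE)
  }
  values <- withSeed(seed, c(rnorm(nNull), rep(outValue, nOut)))
  list(values = values,
       isOutlier = rep(c(FALSE, TRUE), c(nNull, nOut)),
       nNull = nNull, nOut = nOut, outValue = outValue, seed = seed)
}

#' Two-class synthetic count matrix with planted DEGs
#'
#' Emulates a two-class bulk RNA-seq benchmark (a reference-vs-brain style
#' contrast): per-gene baseline abundances are drawn log-normal
#' (\code{2^N(baselineLogMean, baselineLogSd^2)}), a \code{degFraction}
#' share of genes receives a signed log2 fold change with magnitude
#' \code{lfcScale * |N(0,1)|} applied multiplicatively to class B only, and
#' counts are drawn Poisson around the per-class means.  Noise is
#' deliberately Poisson rather than negative-binomial by default -- the
#' selection method under test makes no NB assumption -- with NB available
#' through \code{dispersion} for robustness checks.
#'
#' @param nGenes number of genes (>= 100).
#' @param nPerClass samples per class (>= 2).
#' @param degFraction fraction of genes that are true DEGs, in [0, 1].
#' @param lfcScale scale of the half-normal LFC magnitudes (log2 units).
#' @param baselineLogMean,baselineLogSd mean and SD of per-gene baseline
#'   log2 abundance (defaults 4 and 1.5: median count 16, roughly three
#'   orders of magnitude of dynamic range).
#' @param dispersion optional NB dispersion (\code{size = 1/dispersion});
#'   \code{NULL} (default) keeps pure Poisson noise.
#' @param seed integer seed.
#'
#' @return a list: \code{matrix} (genes x 2*nPerClass counts, dimnames
#'   set), \code{classLabels} (logical, \code{TRUE} = class A, first
#'   \code{nPerClass} columns), \code{isDeg}, \code{lfc} (zero for
#'   non-DEGs), \code{baseline} (per-gene class-A mean), \code{params},
#'   \code{seed}.
#' @examples
#' sim <- simulateTwoClassCounts(nGenes = 500, nPerClass = 4, seed = 1)
#' dim(sim$matrix)
#' @export
simulateTwoClassCounts <- function(nGenes = 2000, nPerClass = 7,
                                   degFraction = 0.1, lfcScale = 2,
                                   baselineLogMean = 4, baselineLogSd = 1.5,
                                   dispersion = NULL, seed = 1) {
  if (nGenes < 100) stop("nGenes must be >= 100", call. = FALSE)
  if (nPerClass < 2) stop("nPerClass must be >= 2", call. = FALSE)
  if (degFraction < 0 || degFraction > 1) {
    stop("degFraction must lie in [0, 1]", call. = FALSE)
  }
  if (lfcScale < 0) stop("lfcScale must be nonnegative", call. = FALSE)
  withSeed(seed, {
    mu <- 2^rnorm(nGenes, baselineLogMean, baselineLogSd)
    nDeg <- round(degFraction * nGenes)
    isDeg <- rep(FALSE, nGenes)
    if (nDeg > 0) isDeg[sample.int(nGenes, nDeg)] <- TRUE
    lfc <- numeric(nGenes)
    lfc[isDeg] <- sample(c(-1, 1), nDeg, replace = TRUE) *
      abs(rnorm(nDeg)) * lfcScale
    muB <- mu * 2^lfc
    draw <- function(m, ncol) {
      lambda <- rep(m, times = ncol)
      cnt <- if (is.null(dispersion)) {
        rpois(length(lambda), lambda)
      } else {
        rnbinom(length(lambda), mu = lambda, size = 1 / dispersion)
      }
      matrix(cnt, nrow = nGenes, ncol = ncol)
    }
    counts <- cbind(draw(mu, nPerClass), draw(muB, nPerClass))
    dimnames(counts) <- list(
      sprintf("gene%05d", seq_len(nGenes)),
      c(sprintf("A%02d", seq_len(nPerClass)),
        sprintf("B%02d", seq_len(nPerClass))))
    list(matrix = counts,
         classLabels = rep(c(TRUE, FALSE), each = nPerClass),
         isDeg = isDeg, lfc = lfc, baseline = mu,
         params = list(nGenes = nGenes, nPerClass = nPerClass,
                       degFraction = degFraction, lfcScale = lfcScale,
                       baselineLogMean = baselineLogMean,
                       baselineLogSd = baselineLogSd,
                       dispersion = dispersion),
         seed = seed)
  })
}

#' Three-mode tensor with a planted condition-specific signal
#'
#' Gaussian background tensor (features x samples x conditions) in which
#' the first \code{signalGenes} features receive a mean shift of total
#' magnitude \code{effect} between treated and control samples, under the
#' \code{signalCondition} only.  Samples split half control / half treated.
#' Emulates infection- or drug-treatment tensor designs where one condition
#' carries the contrast of interest.
#'
#' @param nGenes,nSamples,nConditions tensor extents; \code{nSamples} must
#'   be even and >= 2 (default 10: five control, five treated).
#' @param signalGenes number of planted features (<= \code{nGenes}).
#' @param signalCondition index of the condition carrying the signal.
#' @param effect treated-minus-control mean difference for planted
#'   features (0 for a pure null tensor).
#' @param seed integer seed.
#'
#' @return a list: \code{tensor} (dimnames set), \code{isSignal} (logical
#'   over features), \code{contrast} (+1 treated / -1 control over
#'   samples), \code{signalCondition}, \code{seed}.
#' @export
simulatePlantedTensor <- function(nGenes = 1000, nSamples = 10,
                                  nConditions = 3, signalGenes = 50,
                                  signalCondition = 1, effect = 3,
                                  seed = 1) {
  if (signalGenes > nGenes) {
    stop("signalGenes must not exceed nGenes", call. = FALSE)
  }
  if (signalCondition < 1 || signalCondition > nConditions) {
    stop("signalCondition out of range", call. = FALSE)
  }
  if (nSamples < 2 || nSamples %% 2 != 0) {
    stop("nSamples must be even and >= 2", call. = FALSE)
  }
  withSeed(seed, {
    x <- array(rnorm(nGenes * nSamples * nConditions),
               c(nGenes, nSamples, nConditions))
    contrast <- rep(c(-1, 1), each = nSamples / 2)
    if (signalGenes > 0 && effect != 0) {
      shift <- outer(rep(effect / 2, signalGenes), contrast)
      x[seq_len(signalGenes), , signalCondition] <-
        x[seq_len(signalGenes), , signalCondition] + shift
    }
    dimnames(x) <- list(sprintf("gene%05d", seq_len(nGenes)),
                        sprintf("s%02d", seq_len(nSamples)),
                        sprintf("cond%d", seq_len(nConditions)))
    list(tensor = x,
         isSignal = seq_len(nGenes) <= signalGenes,
         contrast = contrast,
         signalCondition = signalCondition, seed = seed)
  })
}

#' MA-plot demonstration with uniform random expression
#'
#' Draws \code{n} pairs \eqn{(x, y)} i.i.d. uniform on [0, 1], computes the
#' MA coordinates and flags points with \eqn{|x - y|} above the threshold.
#' Illustrates the geometry linking raw differences to fold changes:
#' \eqn{\Delta = y (2^{LFC} - 1)}, so for a fixed LFC the difference --
#' and hence the chance of being flagged -- shrinks with the expression
#' level.
#'
#' @param n number of points.
#' @param deltaThreshold flag points with \eqn{|x - y|} above this value
#'   (default 0.5; at 0.5 about a quarter of the unit square is flagged).
#' @param seed integer seed.
#'
#' @return a data.frame with columns \code{x}, \code{y}, \code{A}
#'   (mean log2), \code{M} (log2 ratio), \code{delta} (\eqn{x - y}) and
#'   \code{flagged}.
#' @examples
#' d <- simulateUniformMA(1000, seed = 1)
#' mean(d$flagged)  # ~0.25
#' @export
simulateUniformMA <- function(n, deltaThreshold = 0.5, seed = 1) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (deltaThreshold < 0) {
    stop("deltaThreshold must be nonnegative", call. = FALSE)
  }
  withSeed(seed, {
    x <- runif(n)
    y <- runif(n)
    data.frame(x = x, y = y,
               A = (log2(x) + log2(y)) / 2,
               M = log2(x / y),
               delta = x - y,
               flagged = abs(x - y) > deltaThreshold)
  })
}
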
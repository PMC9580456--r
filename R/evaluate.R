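#' Confusion-matrix counts for a feature selection
#'
#' Cross-tabulates truth labels (outlier / DEG) against selection flags.
#'
#' @param truth logical vector of ground-truth labels.
#' @param selected logical vector of predictions (same length), e.g.
#'   \code{isSelected(sel)}.
#' @return named integer vector \code{c(tn, fp, fn, tp)}.
#' @examples
#' confusionCounts(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, FALSE))
#' @export
confusionCounts <- function(truth, selected) {
  if (length(truth) != length(selected)) {
    stop("truth and selected must have equal length", call. = FALSE)
  }
  truth <- as.logical(truth)
  selected <- as.logical(selected)
  c(tn = sum(!truth & !selected), fp = sum(!truth & selected),
    fn = sum(truth & !selected), tp = sum(truth & selected))
}

#' Rank-coincidence AUC between two P-value rankings
#'
#' Measures how well one method's P-values retrieve another method's top
#' features: the \code{topK} features with the smallest
#' \code{pReference} are regarded as positives, and the AUC of ranking by
#' \code{pPredictor} (smaller = more positive) is computed through the
#' rank-sum (Mann-Whitney) identity with average ranks for ties.  The
#' statistic is invariant under strictly increasing transforms of
#' \code{pPredictor}.
#'
#' @param pReference numeric vector defining the positives.
#' @param pPredictor numeric vector used for retrieval (same length).
#' @param topK number of reference-top features regarded positive
#'   (default 1000; must be smaller than the vector length).
#' @return AUC in [0, 1].
#' @export
rankCoincidenceAUC <- function(pReference, pPredictor, topK = 1000) {
  n <- length(pReference)
  if (length(pPredictor) != n) {
    stop("pReference and pPredictor must have equal length", call. = FALSE)
  }
  if (topK >= n) stop("topK must be smaller than the number of features",
                      call. = FALSE)
  if (topK < 1) stop("topK must be at least 1", call. = FALSE)
  pos <- rank(pReference, ties.method = "first") <= topK
  r <- rank(-pPredictor, ties.method = "average")
  (sum(r[pos]) - topK * (topK + 1) / 2) / (topK * (n - topK))
}

#' MA-plot coordinates and selection categories
#'
#' Computes, per feature, the mean log2 expression
#' \eqn{A_i = \frac{1}{M}\sum_j \log_2(x_{ij} + c)} and the log2 fold
#' change \eqn{M_i} (class A mean minus class B mean, same pseudocount
#' \eqn{c}), and assigns each feature a selection category from its
#' BH-adjusted P-value at the 0.1 and 0.01 cutoffs (the conventional
#' coloring of these plots: red for 0.01, blue for 0.1).
#'
#' @param x numeric feature-by-sample matrix of (raw, untransformed)
#'   expression values, or a \code{SummarizedExperiment}.
#' @param classLabels logical vector over samples; \code{TRUE} marks class
#'   A.  Both classes must be nonempty.
#' @param adjP numeric vector of BH-adjusted P-values per feature.
#' @param pseudocount offset inside the logs (default 1; the raw-count
#'   convention).
#' @param thresholds two decreasing adjusted-P cutoffs
#'   (default \code{c(0.1, 0.01)}).
#'
#' @return a data.frame with columns \code{featureId}, \code{A}, \code{M},
#'   \code{category} (factor: \code{not_selected}, \code{selected_0.1},
#'   \code{selected_0.01}).
#' @export
maPlotData <- function(x, classLabels, adjP, pseudocount = 1,
                       thresholds = c(0.1, 0.01)) {
  x <- asExpressionMatrix(x)
  classLabels <- as.logical(classLabels)
  if (length(classLabels) != ncol(x)) {
    stop("classLabels must have one entry per sample", call. = FALSE)
  }
  if (!any(classLabels) || all(classLabels)) {
    stop("both classes must be nonempty", call. = FALSE)
  }
  if (length(adjP) != nrow(x)) {
    stop("adjP must have one entry per feature", call. = FALSE)
  }
  l <- log2(x + pseudocount)
  A <- rowMeans(l)
  M <- rowMeans(l[, classLabels, drop = FALSE]) -
    rowMeans(l[, !classLabels, drop = FALSE])
  lv <- c("not_selected",
          paste0("selected_", thresholds[1]),
          paste0("selected_", thresholds[2]))
  category <- factor(ifelse(adjP <= thresholds[2], lv[3],
                     ifelse(adjP <= thresholds[1], lv[2], lv[1])),
                     levels = lv)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  data.frame(featureId = ids, A = A, M = M, category = category,
             row.names = NULL)
}
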
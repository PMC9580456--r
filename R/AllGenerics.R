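#' @rdname MatrixDecomposition-class
#' @param object,x an object.
#' @export
setGeneric("pcScores", function(object) standardGeneric("pcScores"))

#' @rdname MatrixDecomposition-class
#' @export
setGeneric("pcLoadings", function(object) standardGeneric("pcLoadings"))

#' @rdname MatrixDecomposition-class
#' @export
setGeneric("eigenValues", function(object) standardGeneric("eigenValues"))

#' @rdname MatrixDecomposition-class
#' @export
setGeneric("contributions", function(object) standardGeneric("contributions"))

#' @rdname TensorDecomposition-class
#' @param mode integer mode index (1 = feature, 2 = sample, 3 = condition).
#' @export
setGeneric("factorMatrix", function(object, mode) standardGeneric("factorMatrix"))

#' @rdname TensorDecomposition-class
#' @export
setGeneric("coreTensor", function(object) standardGeneric("coreTensor"))

#' @rdname FESelection-class
#' @export
setGeneric("rawP", function(object) standardGeneric("rawP"))

#' @rdname FESelection-class
#' @export
setGeneric("adjustedP", function(object) standardGeneric("adjustedP"))

#' @rdname FESelection-class
#' @export
setGeneric("isSelected", function(object) standardGeneric("isSelected"))

#' @rdname FESelection-class
#' @export
setGeneric("nullSD", function(object) standardGeneric("nullSD"))

#' @rdname FESelection-class
#' @export
setGeneric("selectionThreshold",
           function(object) standardGeneric("selectionThreshold"))

#' @rdname SDOptimization-class
#' @export
setGeneric("sigmaNaive", function(object) standardGeneric("sigmaNaive"))

#' @rdname SDOptimization-class
#' @export
setGeneric("sigmaOpt", function(object) standardGeneric("sigmaOpt"))

#' @rdname SDOptimization-class
#' @export
setGeneric("sigmaRecomputed",
           function(object) standardGeneric("sigmaRecomputed"))

#' @rdname SDOptimization-class
#' @export
setGeneric("objectiveCurve", function(object) standardGeneric("objectiveCurve"))

## ---- accessors ----

#' @rdname MatrixDecomposition-class
#' @export
setMethod("pcScores", "MatrixDecomposition", function(object) object@scores)

#' @rdname MatrixDecomposition-class
#' @export
setMethod("pcLoadings", "MatrixDecomposition", function(object) object@loadings)

#' @rdname MatrixDecomposition-class
#' @export
setMethod("eigenValues", "MatrixDecomposition",
          function(object) object@eigenvalues)

#' @rdname MatrixDecomposition-class
#' @export
setMethod("contributions", "MatrixDecomposition",
          function(object) object@contributions)

#' @rdname TensorDecomposition-class
#' @export
setMethod("factorMatrix", "TensorDecomposition", function(object, mode) {
  stopifnot(length(mode) == 1, mode %in% 1:3)
  object@factors[[mode]]
})

#' @rdname TensorDecomposition-class
#' @export
setMethod("coreTensor", "TensorDecomposition", function(object) object@core)

#' @rdname FESelection-class
#' @export
setMethod("rawP", "FESelection", function(object) object@rawP)

#' @rdname FESelection-class
#' @export
setMethod("adjustedP", "FESelection", function(object) object@adjustedP)

#' @rdname FESelection-class
#' @export
setMethod("isSelected", "FESelection", function(object) object@selected)

#' @rdname FESelection-class
#' @export
setMethod("nullSD", "FESelection", function(object) object@sigma)

#' @rdname FESelection-class
#' @export
setMethod("selectionThreshold", "FESelection",
          function(object) object@threshold)

#' @rdname SDOptimization-class
#' @export
setMethod("sigmaNaive", "SDOptimization", function(object) object@sigmaNaive)

#' @rdname SDOptimization-class
#' @export
setMethod("sigmaOpt", "SDOptimization", function(object) object@sigmaOpt)

#' @rdname SDOptimization-class
#' @export
setMethod("sigmaRecomputed", "SDOptimization",
          function(object) object@sigmaRecomputed)

#' @rdname SDOptimization-class
#' @export
setMethod("objectiveCurve", "SDOptimization", function(object) object@curve)

## ---- show methods ----

#' @rdname MatrixDecomposition-class
#' @export
setMethod("show", "MatrixDecomposition", function(object) {
  cat("MatrixDecomposition:", nrow(object@scores), "features x",
      nrow(object@loadings), "samples,", length(object@eigenvalues),
      "components\n")
  k <- min(5L, length(object@eigenvalues))
  cat("  top contributions:",
      paste(sprintf("%.3f", object@contributions[seq_len(k)]),
            collapse = " "), "\n")
})

#' @rdname TensorDecomposition-class
#' @export
setMethod("show", "TensorDecomposition", function(object) {
  d <- vapply(object@factors, nrow, integer(1))
  cat("TensorDecomposition:", paste(d, collapse = " x "),
      "tensor; core", paste(dim(object@core), collapse = " x "), "\n")
})

#' @rdname FESelection-class
#' @export
setMethod("show", "FESelection", function(object) {
  cat("FESelection:", length(object@rawP), "features,",
      sum(object@selected), "selected at adjusted P <=",
      object@threshold, "\n")
  if (!is.na(object@sigma[1])) cat("  null SD:", object@sigma, "\n")
})

#' @rdname SDOptimization-class
#' @export
setMethod("show", "SDOptimization", function(object) {
  cat("SDOptimization\n")
  cat("  naive SD:     ", format(object@sigmaNaive), "\n")
  cat("  optimized SD: ", format(object@sigmaOpt), "\n")
  cat("  recomputed SD:", format(object@sigmaRecomputed), "\n")
  cat("  selected at optimum:", object@nSelectedAtOpt,
      sprintf("(adjusted P0 = %g, %d bins)\n", object@p0, object@nBins))
})
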
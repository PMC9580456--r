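#' Build a pipeline run configuration
#'
#' Collects and validates everything a [runPipeline()] call needs.  A
#' configuration can also be read from a YAML file (see
#' [readPipelineConfig()]); explicitly supplied arguments win over file
#' values.
#'
#' @param analysis \code{"pca"} (matrix decomposition), \code{"tensor"}
#'   (HOSVD) or \code{"calibrate"} (SD optimization of a supplied score
#'   vector).
#' @param counts for \code{"pca"}: path to a count table, a matrix, or a
#'   \code{SummarizedExperiment}.
#' @param tensor for \code{"tensor"}: path to a long-format table or a
#'   3-mode array.
#' @param scores for \code{"calibrate"}: numeric vector, or path to a
#'   one-column table of scores.
#' @param target numeric/logical vector over samples defining the contrast
#'   (used in correlation mode).
#' @param targetCondition optional vector over conditions (tensor only).
#' @param design optional path to a TSV with sample annotations; used with
#'   \code{targetColumn} when \code{target} is not given directly.
#' @param targetColumn column of \code{design} holding the contrast.
#' @param component optional explicit component index (\eqn{\ell}) or
#'   \code{c(l1, l2, l3)}; bypasses correlation matching.
#' @param p0 adjusted-P threshold inside the SD-optimization objective.
#' @param fdr adjusted-P threshold for the final selection (default 0.01;
#'   0.1 is conventional for tensor analyses).
#' @param nBins histogram bins for the objective.
#' @param filterMode row filter applied to count input
#'   (see [filterCounts()]).
#' @param log2Transform log2-transform counts before standardization.
#' @param pseudocount offset for the log transform and the MA plot.
#' @param seed integer seed recorded with the run (the pipeline itself is
#'   deterministic; the seed is metadata for provenance).
#' @param outDir optional output directory; when set, the run writes
#'   \code{selection.tsv}, \code{sd_curve.tsv}, \code{maplot.tsv} (when a
#'   two-class contrast is available) and \code{summary.json}.
#'
#' @return a validated list of class \code{"feConfig"}.
#' @export
feConfig <- function(analysis = c("pca", "tensor", "calibrate"),
                     counts = NULL, tensor = NULL, scores = NULL,
                     target = NULL, targetCondition = NULL,
                     design = NULL, targetColumn = NULL,
                     component = NULL,
                     p0 = 0.01, fdr = 0.01, nBins = 100,
                     filterMode = "drop_all_zero",
                     log2Transform = FALSE, pseudocount = 1,
                     seed = NULL, outDir = NULL) {
  analysis <- match.arg(analysis)
  for (thr in c(p0 = p0, fdr = fdr)) {
    if (thr <= 0 || thr >= 1) {
      stop("thresholds must lie in (0, 1)", call. = FALSE)
    }
  }
  cfg <- list(analysis = analysis, counts = counts, tensor = tensor,
              scores = scores, target = target,
              targetCondition = targetCondition, design = design,
              targetColumn = targetColumn, component = component,
              p0 = p0, fdr = fdr, nBins = nBins, filterMode = filterMode,
              log2Transform = log2Transform, pseudocount = pseudocount,
              seed = seed, outDir = outDir)
  class(cfg) <- "feConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML keys mirror the [feConfig()] arguments.  Values supplied in
#' \code{...} override the file.
#'
#' @param path YAML file.
#' @param ... overrides passed on to [feConfig()].
#' @return a \code{"feConfig"} list.
#' @export
readPipelineConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  dots <- list(...)
  y[names(dots)] <- dots
  do.call(feConfig, y)
}

# stable hash of the replay-relevant configuration (input objects replaced
# by summaries; the output location does not affect the hash)
configHash <- function(cfg) {
  flat <- cfg[setdiff(names(cfg), "outDir")]
  for (f in c("counts", "tensor", "scores")) {
    if (!is.null(flat[[f]]) && !is.character(flat[[f]])) {
      flat[[f]] <- c(class(flat[[f]])[1],
                     paste(dim(flat[[f]]) %||% length(flat[[f]]),
                           collapse = "x"))
    }
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(flat, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

resolveTarget <- function(cfg, sampleIds) {
  if (!is.null(cfg$target)) {
    tg <- cfg$target
    if (is.logical(tg)) tg <- ifelse(tg, 1, -1)
    return(as.numeric(tg))
  }
  if (!is.null(cfg$design) && !is.null(cfg$targetColumn)) {
    d <- if (is.character(cfg$design)) {
      utils::read.table(cfg$design, header = TRUE, sep = "\t",
                        check.names = FALSE, stringsAsFactors = FALSE)
    } else as.data.frame(cfg$design)
    if (!cfg$targetColumn %in% names(d)) {
      stop("targetColumn '", cfg$targetColumn, "' not found in design",
           call. = FALSE)
    }
    tg <- d[[cfg$targetColumn]]
    if (!is.null(sampleIds) && "sample" %in% names(d)) {
      tg <- tg[match(sampleIds, d$sample)]
    }
    if (is.character(tg) || is.factor(tg) || is.logical(tg)) {
      tg <- as.numeric(factor(tg))
    }
    return(as.numeric(tg))
  }
  NULL
}

#' Run the unsupervised feature-extraction pipeline
#'
#' Executes standardize, decompose, axis selection, SD optimization,
#' chi-squared P-value attribution at the optimized SD, BH adjustment and
#' selection, and (for two-class matrix runs) MA-plot construction.  Given
#' identical inputs and configuration the run is bit-identical.
#'
#' @param config a \code{"feConfig"} list from [feConfig()] or
#'   [readPipelineConfig()].
#'
#' @return a list with elements \code{selection} ([FESelection-class]),
#'   \code{sdOptimization} ([SDOptimization-class]), \code{decomposition}
#'   (when applicable), \code{axes}, \code{featureIds}, \code{maplot}
#'   (or \code{NULL}), \code{summary} (a flat list recording the sigmas,
#'   counts, thresholds, seed and config hash), and \code{files} (paths
#'   written, when \code{outDir} is set).
#'
#' @examples
#' mix <- simulateGaussianOutliers(seed = 1)
#' res <- runPipeline(feConfig("calibrate", scores = mix$values))
#' res$summary$nSelected
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "feConfig"))
  hash <- configHash(config)
  decomposition <- NULL
  axes <- NULL
  maplot <- NULL
  rawMatrix <- NULL
  classLabels <- NULL

  if (config$analysis == "calibrate") {
    u <- config$scores
    if (is.character(u)) {
      u <- utils::read.table(u, header = FALSE)[[1]]
    }
    u <- as.numeric(u)
    featureIds <- names(config$scores) %||% as.character(seq_along(u))
  } else if (config$analysis == "pca") {
    cn <- config$counts
    if (is.character(cn)) cn <- readCountMatrix(cn, config$filterMode)
    m <- asExpressionMatrix(cn)
    if (!is.character(config$counts)) {
      m <- filterCounts(m, config$filterMode)$matrix
    }
    rawMatrix <- m
    featureIds <- rownames(m) %||% as.character(seq_len(nrow(m)))
    x <- standardizeMatrix(m, log2Transform = config$log2Transform,
                           pseudocount = config$pseudocount)
    decomposition <- pcaDecompose(x)
    target <- resolveTarget(config, colnames(m))
    if (!is.null(config$component)) {
      axes <- selectAxes(decomposition, mode = "explicit",
                         explicitIndices = config$component)
    } else if (!is.null(target)) {
      axes <- selectAxes(decomposition, targetSample = target)
      if (length(unique(target)) == 2) classLabels <- target == max(target)
    } else {
      stop("component selection is ambiguous: supply a target (or design/",
           "targetColumn) or an explicit component index", call. = FALSE)
    }
    u <- pcScores(decomposition)[, axes$feature]
  } else { # tensor
    tn <- config$tensor
    if (is.character(tn)) tn <- readTensorLong(tn)
    featureIds <- dimnames(tn)[[1]] %||% as.character(seq_len(dim(tn)[1]))
    x <- standardizeTensor(tn)
    decomposition <- hosvd(x)
    target <- resolveTarget(config, dimnames(tn)[[2]])
    if (!is.null(config$component)) {
      axes <- selectAxes(decomposition, mode = "explicit",
                         explicitIndices = config$component)
    } else if (!is.null(target)) {
      axes <- selectAxes(decomposition, targetSample = target,
                         targetCondition = config$targetCondition)
    } else {
      stop("component selection is ambiguous: supply a target (or design/",
           "targetColumn) or explicit component indices", call. = FALSE)
    }
    u <- factorMatrix(decomposition, 1)[, axes$feature]
  }

  opt <- optimizeSD(u, p0 = config$p0, nBins = config$nBins)
  selection <- attributePvalues(u, sigmaOpt(opt), threshold = config$fdr)

  if (!is.null(rawMatrix) && !is.null(classLabels)) {
    maplot <- maPlotData(rawMatrix, classLabels, adjustedP(selection),
                         pseudocount = config$pseudocount)
  }

  summary <- list(
    analysis = config$analysis,
    nFeatures = length(u),
    featureAxis = axes$feature %||% NA_integer_,
    sigmaNaive = sigmaNaive(opt),
    sigmaOpt = sigmaOpt(opt),
    sigmaRecomputed = sigmaRecomputed(opt),
    nSelected = sum(isSelected(selection)),
    p0 = config$p0, fdr = config$fdr, nBins = config$nBins,
    filterMode = config$filterMode,
    log2Transform = config$log2Transform,
    pseudocount = config$pseudocount,
    seed = config$seed %||% NA_integer_,
    configHash = hash)

  files <- NULL
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    stamp <- sprintf("sigmaFE run config=%s seed=%s", hash,
                     config$seed %||% "NA")
    files <- c(
      selection = writeSelection(selection,
        file.path(config$outDir, "selection.tsv"), featureIds, stamp),
      sd_curve = writeTSVWithHeader(objectiveCurve(opt),
        file.path(config$outDir, "sd_curve.tsv"), stamp))
    if (!is.null(maplot)) {
      files["maplot"] <- writeTSVWithHeader(maplot,
        file.path(config$outDir, "maplot.tsv"), stamp)
    }
    jsonlite::write_json(summary,
      file.path(config$outDir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files["summary"] <- file.path(config$outDir, "summary.json")
  }

  list(selection = selection, sdOptimization = opt,
       decomposition = decomposition, axes = axes,
       featureIds = featureIds, maplot = maplot,
       summary = summary, files = files)
}
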
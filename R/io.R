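#' Filter a count matrix by expression rules
#'
#' Applies the row-filtering rules used before decomposition: rows whose
#' feature ID starts with \code{"__"} (aggregate rows emitted by counting
#' tools, e.g. \code{__no_feature}, \code{__ambiguous}) are always dropped;
#' then either all-zero rows are removed (\code{"drop_all_zero"}), only
#' rows positive in every sample are kept (\code{"require_all_nonzero"}),
#' or nothing further is done (\code{"none"}).
#'
#' @param x numeric feature-by-sample matrix with rownames.
#' @param filterMode one of \code{"drop_all_zero"} (default),
#'   \code{"require_all_nonzero"}, \code{"none"}.
#' @return a list: \code{matrix} (the filtered matrix) and \code{report}
#'   (named counts of rows dropped per rule and rows kept).
#' @export
filterCounts <- function(x, filterMode = c("drop_all_zero",
                                           "require_all_nonzero", "none")) {
  filterMode <- match.arg(filterMode)
  x <- as.matrix(x)
  special <- !is.null(rownames(x)) & startsWith(rownames(x) %||% "", "__")
  nSpecial <- sum(special)
  x <- x[!special, , drop = FALSE]
  nRule <- 0L
  if (filterMode == "drop_all_zero") {
    keep <- rowSums(x != 0) > 0
    nRule <- sum(!keep)
    x <- x[keep, , drop = FALSE]
  } else if (filterMode == "require_all_nonzero") {
    keep <- rowSums(x > 0) == ncol(x)
    nRule <- sum(!keep)
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) == 0) {
    stop("no features left after filtering", call. = FALSE)
  }
  list(matrix = x,
       report = c(special_rows_dropped = nSpecial,
                  filter_rows_dropped = nRule,
                  rows_kept = nrow(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a count matrix from TSV/CSV or MatrixMarket
#'
#' Reads a feature-by-sample count/expression table.  Delimited files must
#' have feature IDs in the first column and sample IDs in the header; a
#' \code{.mtx} MatrixMarket file is read with its \code{<path>.rows} /
#' \code{<path>.cols} sidecars (one ID per line).  Aggregate rows whose ID
#' starts with \code{"__"} are always dropped, then \code{filterMode} is
#' applied (see [filterCounts()]).
#'
#' @param path file path (\code{.tsv}, \code{.txt}, \code{.csv} or
#'   \code{.mtx}).
#' @inheritParams filterCounts
#' @return a \code{SummarizedExperiment} with a single \code{counts} assay;
#'   the filter report is stored in \code{metadata(.)$filterReport}.
#' @export
readCountMatrix <- function(path, filterMode = c("drop_all_zero",
                                                 "require_all_nonzero",
                                                 "none")) {
  filterMode <- match.arg(filterMode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    rows <- paste0(path, ".rows")
    cols <- paste0(path, ".cols")
    if (!file.exists(rows) || !file.exists(cols)) {
      stop("MatrixMarket input needs '", rows, "' and '", cols,
           "' sidecar files", call. = FALSE)
    }
    rownames(m) <- readLines(rows)
    colnames(m) <- readLines(cols)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, colClasses = "character",
                            quote = "\"", comment.char = "")
    ids <- df[[1]]
    vals <- df[, -1, drop = FALSE]
    num <- suppressWarnings(
      vapply(vals, as.numeric, numeric(nrow(vals))))
    if (nrow(vals) == 1) num <- matrix(num, nrow = 1)
    bad <- which(is.na(num) & !(vals == "NA"), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   as.matrix(vals)[bad[1, , drop = FALSE]],
                   ids[bad[1, 1]], colnames(vals)[bad[1, 2]]),
           call. = FALSE)
    }
    m <- num
    rownames(m) <- ids
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate feature IDs: ",
         paste(unique(rownames(m)[duplicated(rownames(m))])[1:3],
               collapse = ", "), call. = FALSE)
  }
  assertFinite(m, "count matrix")
  fl <- filterCounts(m, filterMode)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = fl$matrix))
  S4Vectors::metadata(se)$filterReport <- fl$report
  se
}

#' Read a three-mode tensor from a long-format table
#'
#' Expects a TSV/CSV with columns \code{feature}, \code{sample},
#' \code{condition}, \code{value} (header required).  The table must cover
#' every (feature, sample, condition) cell exactly once; missing cells are
#' an error (no imputation).
#'
#' @param path file path.
#' @return a numeric 3-mode array with dimnames.
#' @export
readTensorLong <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("feature", "sample", "condition", "value")
  if (!all(need %in% names(df))) {
    stop("long-format tensor needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  f <- unique(df$feature)
  s <- unique(df$sample)
  k <- unique(df$condition)
  if (nrow(df) != length(f) * length(s) * length(k)) {
    stop("incomplete tensor: expected ",
         length(f) * length(s) * length(k), " cells, got ", nrow(df),
         " (missing cells are not imputed)", call. = FALSE)
  }
  if (anyDuplicated(df[c("feature", "sample", "condition")])) {
    stop("duplicate (feature, sample, condition) cells", call. = FALSE)
  }
  if (!is.numeric(df$value)) stop("value column must be numeric",
                                  call. = FALSE)
  x <- array(NA_real_, c(length(f), length(s), length(k)),
             dimnames = list(f, s, k))
  x[cbind(match(df$feature, f), match(df$sample, s),
          match(df$condition, k))] <- df$value
  assertFinite(x, "tensor")
  x
}

# write a TSV with a provenance comment line
writeTSVWithHeader <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write decomposition factors as TSV
#'
#' One file per factor: features/samples in rows, components in columns
#' (headers \code{PC1...} for a matrix decomposition, \code{L1...} per mode
#' for a tensor decomposition).
#'
#' @param decomposition a [MatrixDecomposition-class] or
#'   [TensorDecomposition-class] object.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @param comment optional provenance string written as a leading
#'   \code{#} line.
#' @return invisibly, the paths written.
#' @export
writeDecomposition <- function(decomposition, dir, prefix = "decomposition",
                               comment = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  asDf <- function(m, idcol) {
    data.frame(id = rownames(m) %||% as.character(seq_len(nrow(m))),
               as.data.frame(m, optional = TRUE),
               check.names = FALSE)
  }
  paths <- character()
  if (methods::is(decomposition, "MatrixDecomposition")) {
    paths <- c(
      scores = writeTSVWithHeader(asDf(decomposition@scores),
        file.path(dir, paste0(prefix, "_scores.tsv")), comment),
      loadings = writeTSVWithHeader(asDf(decomposition@loadings),
        file.path(dir, paste0(prefix, "_loadings.tsv")), comment))
  } else if (methods::is(decomposition, "TensorDecomposition")) {
    nm <- c("feature", "sample", "condition")
    for (n in 1:3) {
      paths[nm[n]] <- writeTSVWithHeader(asDf(decomposition@factors[[n]]),
        file.path(dir, paste0(prefix, "_factor_", nm[n], ".tsv")), comment)
    }
  } else {
    stop("unsupported decomposition object", call. = FALSE)
  }
  invisible(paths)
}

#' Write a feature selection as TSV
#'
#' Columns: \code{feature_id}, \code{score_u}, \code{raw_p},
#' \code{adjusted_p}, \code{selected} (0/1), in input row order.
#'
#' @param selection an [FESelection-class] object.
#' @param path output file.
#' @param featureIds optional character vector of feature IDs.
#' @param comment optional provenance string.
#' @return invisibly, \code{path}.
#' @export
writeSelection <- function(selection, path, featureIds = NULL,
                           comment = NULL) {
  n <- length(selection@rawP)
  if (is.null(featureIds)) featureIds <- as.character(seq_len(n))
  df <- data.frame(feature_id = featureIds,
                   score_u = selection@u,
                   raw_p = selection@rawP,
                   adjusted_p = selection@adjustedP,
                   selected = as.integer(selection@selected))
  writeTSVWithHeader(df, path, comment)
}
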
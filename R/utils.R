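# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

assertFinite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(x)
}

assertScalarPositive <- function(x, what) {
  if (length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(what, " must be a single positive number", call. = FALSE)
  }
  invisible(x)
}

# coerce a SummarizedExperiment (first assay) or matrix-like to a base matrix
asExpressionMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    x <- SummarizedExperiment::assay(x, 1)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}
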
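# Independent oracles used to cross-check the implementation.

# Benjamini-Hochberg by direct enumeration of min_{k >= i} p_(k) * n / k.
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[o[i]] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  q
}

# PCA through the dense N x N feature gram matrix (only for small N).
gramPCA <- function(x) {
  e <- eigen(tcrossprod(x), symmetric = TRUE)
  k <- min(dim(x))
  list(values = e$values[seq_len(k)],
       vectors = e$vectors[, seq_len(k), drop = FALSE])
}

# align the sign of each column of b to a (for comparisons up to sign)
matchSign <- function(a, b) {
  for (l in seq_len(ncol(b))) {
    if (sum(a[, l] * b[, l]) < 0) b[, l] <- -b[, l]
  }
  b
}

# dense per-mode unfolding SVD (oracle for hosvd factors)
oracleUnfoldingSVD <- function(x, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(1:3, mode))
  svd(matrix(aperm(x, perm), nrow = d[mode]))$u
}

randomStandardized <- function(n, m) {
  standardizeMatrix(matrix(rnorm(n * m), n, m))
}
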
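# Shared in-code fixtures. All randomness is seeded at the call site.

# beta feature matrix with exactly controllable values
beta_fm <- function(values, feature_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  if (!is.null(feature_ids)) rownames(m) <- feature_ids
  if (!is.null(sample_ids)) colnames(m) <- sample_ids
  feature_matrix(m, "dname_beta")
}

# small labelled count matrix with two groups and hand-set rows
toy_cells <- function(values, labels) {
  cell_matrix(as.matrix(values), labels = labels)
}

# out-group cell values whose sample covariance is EXACTLY diagonal:
# residual directions orthonormal and orthogonal to the constant vector
diagonal_cov_outgroup <- function(means, sds, n_cells, seed) {
  set.seed(seed)
  p <- length(means)
  stopifnot(n_cells >= p + 1)
  Q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n_cells * p), n_cells, p))))[, -1, drop = FALSE]
  # columns of Q: orthonormal, zero-sum; residual for feature i has sd sds[i]
  R <- t(Q) * (sds * sqrt(n_cells - 1))
  sweep(R, 1, means, `+`)
}

# uniform random column-stochastic matrix
random_props <- function(k, n, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(k * n), k, n)
  sweep(W, 2, colSums(W), `/`)
}
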
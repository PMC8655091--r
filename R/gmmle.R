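# GMM-LE clustering: degree-corrected regularised spectral embedding of a
# cell-cell similarity graph, with cluster assignment by a Gaussian mixture
# model fitted in the Laplacian eigenspace (maximum posterior probability),
# plus marker-set scoring to give clusters provisional cell-type names.

#' Build a cosine kNN similarity graph over cells
#'
#' Columns (cells) are log-transformed (`log(1+x)`, for count data), pairwise
#' cosine similarities computed, and each cell keeps its `n_neighbors`
#' strongest neighbours; the graph is symmetrised by the elementwise maximum
#' and the diagonal zeroed. The number of connected components is attached.
#'
#' @param Y a [cell_matrix()] or [feature_matrix()]; cells/samples in columns.
#' @param n_neighbors neighbours kept per cell (default 50).
#' @param log_transform apply `log1p` before computing similarities
#'   (default `TRUE`).
#' @return symmetric non-negative adjacency matrix with attribute
#'   `"n_components"`.
#' @export
build_graph <- function(Y, n_neighbors = 50, log_transform = TRUE) {
  v <- if (inherits(Y, "cell_matrix") || inherits(Y, "feature_matrix")) Y$values else as.matrix(Y)
  m <- ncol(v)
  if (m < n_neighbors + 1) {
    stop(sprintf("need at least n_neighbors+1 = %d cells, have %d", n_neighbors + 1, m),
         call. = FALSE)
  }
  if (log_transform) v <- log1p(v)
  nrm <- sqrt(colSums(v^2))
  nrm[nrm == 0] <- 1
  u <- sweep(v, 2, nrm, `/`)
  S <- crossprod(u)
  S <- pmax(S, 0)
  diag(S) <- 0
  keep <- matrix(FALSE, m, m)
  for (j in seq_len(m)) {
    o <- order(S[, j], decreasing = TRUE)[seq_len(n_neighbors)]
    keep[o, j] <- TRUE
  }
  W <- S * keep
  W <- pmax(W, t(W))
  dimnames(W) <- list(colnames(v), colnames(v))
  # connected components by breadth-first search
  comp <- integer(m); cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      frontier <- s
      comp[s] <- cur
      while (length(frontier)) {
        nb <- which(rowSums(W[, frontier, drop = FALSE] > 0) > 0 & comp == 0L)
        comp[nb] <- cur
        frontier <- nb
      }
    }
  }
  log_msg(sprintf("graph: %d cells, %d components", m, cur))
  structure(W, n_components = cur)
}

#' Regularised Laplacian eigenspace embedding
#'
#' Computes the top-`K` eigenvectors of the regularised normalised adjacency
#' \deqn{D_\tau^{-1/2} A D_\tau^{-1/2}, \quad D_\tau = D + \tau I,}
#' where `D` is the degree diagonal and the regulariser `tau` defaults to the
#' mean degree (the convention of regularised spectral clustering, which
#' stabilises the spectrum when degrees are uneven). Rows of the eigenvector
#' matrix are normalised to unit length — the degree correction, projecting
#' out degree heterogeneity — with all-zero rows left at zero and flagged.
#' Each eigenvector's sign is fixed by making its largest-magnitude entry
#' positive, so the embedding is deterministic.
#'
#' @param adjacency symmetric non-negative matrix (e.g. from [build_graph()]).
#' @param K embedding dimensions (>= 2).
#' @param tau regulariser, or `"auto"` for the mean degree.
#' @return an object of class `lap_embedding`: `coordinates` (cells x K),
#'   `eigenvalues`, `tau`, `zero_rows`.
#' @export
laplacian_eigenspace <- function(adjacency, K, tau = "auto") {
  A <- as.matrix(adjacency)
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-10)) || min(A) < 0) {
    stop("adjacency must be symmetric and non-negative", call. = FALSE)
  }
  stopifnot(K >= 2, K <= nrow(A))
  deg <- rowSums(A)
  if (identical(tau, "auto")) tau <- mean(deg)
  stopifnot(is.numeric(tau), tau >= 0)
  inv_sqrt <- 1 / sqrt(deg + tau)
  if (any(!is.finite(inv_sqrt))) {
    stop("zero regularised degree; supply tau > 0", call. = FALSE)
  }
  M <- A * tcrossprod(inv_sqrt)
  eig <- tryCatch(eigen(M, symmetric = TRUE),
                  error = function(e) stop("eigendecomposition failed: ",
                                           conditionMessage(e), call. = FALSE))
  U <- eig$vectors[, seq_len(K), drop = FALSE]
  vals <- eig$values[seq_len(K)]
  for (j in seq_len(K)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  rn <- sqrt(rowSums(U^2))
  zero_rows <- rn < 1e-12
  rs <- ifelse(zero_rows, 1, rn)
  coords <- U / rs
  rownames(coords) <- rownames(A)
  structure(list(coordinates = coords, eigenvalues = vals, tau = tau,
                 zero_rows = zero_rows),
            class = "lap_embedding")
}

#' @export
print.lap_embedding <- function(x, ...) {
  cat(sprintf("<lap_embedding> %d cells in %d dimensions, tau = %.4g\n",
              nrow(x$coordinates), ncol(x$coordinates), x$tau))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Gaussian-mixture clustering in the Laplacian eigenspace
#'
#' Fits a Gaussian mixture model (full covariance per component, EM) to the
#' embedding rows and assigns each cell to the cluster with maximum posterior
#' probability. Model fitting is via `mclust`; if the default full-covariance
#' model degenerates, progressively simpler covariance structures are tried
#' before failing.
#'
#' @param E a `lap_embedding` (or a plain coordinate matrix).
#' @param n_clusters number of mixture components.
#' @param seed RNG seed for reproducibility of the fit.
#' @return an object of class `gmm_assignment`: `labels` (integer cluster per
#'   cell), `posterior` (cells x clusters, rows sum to 1), `log_likelihood`,
#'   `bic`, `model_name`.
#' @export
gmm_le_cluster <- function(E, n_clusters, seed = 1) {
  coords <- if (inherits(E, "lap_embedding")) E$coordinates else as.matrix(E)
  stopifnot(n_clusters >= 1)
  m <- nrow(coords)
  if (n_clusters == 1) {
    post <- matrix(1, m, 1, dimnames = list(rownames(coords), "1"))
    return(structure(list(labels = stats::setNames(rep(1L, m), rownames(coords)),
                          posterior = post, log_likelihood = NA_real_,
                          bic = NA_real_, model_name = "single"),
                     class = "gmm_assignment"))
  }
  set.seed(seed)
  # a graph with <= n_clusters connected components embeds as exact point
  # masses; the mixture is then degenerate and the assignment is just the
  # partition of distinct embedding rows
  key <- apply(round(coords, 8), 1, paste, collapse = ",")
  if (length(unique(key)) <= n_clusters) {
    lab <- as.integer(factor(key, levels = unique(key)))
    post <- diag(max(lab))[lab, , drop = FALSE]
    dimnames(post) <- list(rownames(coords), seq_len(max(lab)))
    return(structure(list(labels = stats::setNames(lab, rownames(coords)),
                          posterior = post, log_likelihood = NA_real_,
                          bic = NA_real_, model_name = "exact"),
                     class = "gmm_assignment"))
  }
  fit <- NULL
  for (attempt in list(list(coords, "VVV"), list(coords, NULL),
                       list(coords + stats::rnorm(length(coords),
                                                  sd = 1e-6 * stats::sd(coords)),
                            NULL))) {
    fit <- suppressWarnings(
      Mclust(attempt[[1]], G = n_clusters, modelNames = attempt[[2]],
             verbose = FALSE))
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("all Gaussian mixture fits degenerated", call. = FALSE)
  post <- fit$z
  rownames(post) <- rownames(coords)
  labels <- apply(post, 1, which.max)
  structure(list(labels = stats::setNames(as.integer(labels), rownames(coords)),
                 posterior = post,
                 log_likelihood = fit$loglik,
                 bic = fit$bic,
                 model_name = fit$modelName),
            class = "gmm_assignment")
}

#' @export
print.gmm_assignment <- function(x, ...) {
  cat(sprintf("<gmm_assignment> %d cells, %d clusters (model %s)\n",
              length(x$labels), ncol(x$posterior), x$model_name))
  print(table(cluster = x$labels))
  invisible(x)
}

#' End-to-end GMM-LE clustering of a single-cell matrix
#'
#' Convenience wrapper: [build_graph()] then [laplacian_eigenspace()] (with
#' `K = n_clusters`) then [gmm_le_cluster()].
#'
#' @param Y a [cell_matrix()].
#' @param n_clusters number of clusters.
#' @param n_neighbors kNN graph neighbourhood size (default 50).
#' @param tau Laplacian regulariser (default `"auto"`, the mean degree).
#' @param seed RNG seed.
#' @return a `gmm_assignment`, with the embedding attached as attribute
#'   `"embedding"`.
#' @export
gmm_le <- function(Y, n_clusters, n_neighbors = 50, tau = "auto", seed = 1) {
  W <- build_graph(Y, n_neighbors = n_neighbors)
  E <- laplacian_eigenspace(W, K = max(2, n_clusters), tau = tau)
  a <- gmm_le_cluster(E, n_clusters, seed = seed)
  attr(a, "embedding") <- E
  a
}

#' Score clusters against marker gene sets
#'
#' For naming clusters: score(cluster, set) is the mean over the cluster's
#' cells of the mean `log(1 + count)` over the set's genes. Markers that do
#' not resolve against the matrix's features are dropped (and logged); a set
#' with no resolvable marker is an error. Each cluster is provisionally named
#' by its argmax set; clusters whose scores are all equal (e.g. all-zero
#' counts) are flagged ambiguous.
#'
#' @param Y a [cell_matrix()].
#' @param assignment a `gmm_assignment` (or an integer/character label
#'   vector, one per cell).
#' @param markers a [marker_sets()] object.
#' @return a data frame with one row per (cluster, marker set) and columns
#'   `cluster`, `marker_set`, `score`; attributes `"cluster_names"` (argmax
#'   set per cluster) and `"ambiguous"`.
#' @export
score_marker_sets <- function(Y, assignment, markers) {
  stopifnot(inherits(Y, "cell_matrix"), inherits(markers, "marker_sets"))
  labels <- if (inherits(assignment, "gmm_assignment")) assignment$labels else assignment
  if (length(labels) != ncol(Y$values)) stop("need one label per cell", call. = FALSE)
  resolved <- lapply(markers, intersect, rownames(Y$values))
  dropped <- mapply(function(a, b) length(a) - length(b), markers, resolved)
  if (any(dropped > 0)) {
    log_msg(sprintf("dropped %d unresolved marker(s) across %d set(s)",
                    sum(dropped), sum(dropped > 0)))
  }
  empty <- names(resolved)[vapply(resolved, length, 1L) == 0]
  if (length(empty)) {
    stop("no resolvable markers in set(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  lg <- log1p(Y$values)
  clusters <- sort(unique(labels))
  rows <- expand.grid(cluster = clusters, marker_set = names(resolved),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rows$score <- mapply(function(cl, st) {
    mean(colMeans(lg[resolved[[st]], labels == cl, drop = FALSE]))
  }, rows$cluster, rows$marker_set)
  sc <- matrix(rows$score, nrow = length(clusters),
               dimnames = list(clusters, names(resolved)))
  amb <- apply(sc, 1, function(r) diff(range(r)) < .Machine$double.eps^0.5)
  nm <- colnames(sc)[apply(sc, 1, which.max)]
  nm[amb] <- NA_character_
  attr(rows, "cluster_names") <- stats::setNames(nm, clusters)
  attr(rows, "ambiguous") <- stats::setNames(amb, clusters)
  rows
}
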
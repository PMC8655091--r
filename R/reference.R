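# Signature-matrix construction from labelled single-cell data.
#
# Two rankings are offered for choosing the p' discriminative features that
# define A: a modified Mahalanobis statistic that discounts redundancy among
# correlated features, and a negative-binomial differential-expression test
# (one cell type vs all others pooled). Either way, A's columns are the
# per-type mean profiles over the union of the per-type top-ranked features.
# For purified DNAme profiles a separate three-criteria locus selection is
# provided.

group_split <- function(Y, target_type) {
  if (is.null(Y$labels)) stop("cell matrix must carry labels", call. = FALSE)
  if (!target_type %in% Y$labels) {
    stop("target type '", target_type, "' not present in labels", call. = FALSE)
  }
  in_idx <- which(Y$labels == target_type)
  out_idx <- which(Y$labels != target_type)
  list(in_idx = in_idx, out_idx = out_idx)
}

#' Pre-select candidate features for a cell type
#'
#' Scores each feature by the standardised in-group/out-group mean difference
#' \deqn{(\bar Y_{in} - \bar Y_{out}) / \sqrt{V(Y_{out})}}
#' where the mean and variance are over cells of the target type and all other
#' cells pooled. Features exceeding `lambda` pass; when `lambda` is `NULL`
#' (the default) the `top_n` highest-scoring features pass instead, which
#' bounds the size of the covariance estimated by the Mahalanobis refinement.
#' A feature with zero out-group variance but a non-zero mean difference is a
#' perfect discriminator and scores `Inf` (sign of the difference).
#'
#' @param Y a labelled [cell_matrix()].
#' @param target_type a label present in `Y`.
#' @param lambda threshold on the statistic, or `NULL` to keep `top_n`.
#' @param top_n number of features kept when `lambda` is `NULL` (default 1000).
#' @return character vector of passing feature IDs, with the statistic
#'   attached as attribute `"statistic"` (named, all features).
#' @export
preselect_features <- function(Y, target_type, lambda = NULL, top_n = 1000) {
  g <- group_split(Y, target_type)
  vin <- Y$values[, g$in_idx, drop = FALSE]
  vout <- Y$values[, g$out_idx, drop = FALSE]
  mean_in <- rowMeans(vin)
  mean_out <- rowMeans(vout)
  var_out <- apply(vout, 1, stats::var)
  diff <- mean_in - mean_out
  stat <- diff / sqrt(var_out)
  zero <- var_out == 0
  stat[zero] <- sign(diff[zero]) * Inf
  stat[zero & diff == 0] <- 0
  names(stat) <- rownames(Y$values)
  if (is.null(lambda)) {
    keep <- names(stat)[order(-stat, names(stat))][seq_len(min(top_n, length(stat)))]
  } else {
    keep <- names(stat)[stat > lambda]
  }
  k <- length(unique(Y$labels))
  if (length(keep) < k) {
    stop(sprintf("only %d features pass pre-selection (need >= %d cell types); lower lambda",
                 length(keep), k), call. = FALSE)
  }
  structure(keep, statistic = stat)
}

#' Modified Mahalanobis scores for a difference vector
#'
#' Computes \eqn{d = \Sigma^{-1} (\delta \circ |\delta|)}: the signed-squared
#' mean-difference vector whitened by the (regularised) out-group covariance,
#' so that features that merely duplicate the signal of a correlated
#' neighbour are discounted. The system is solved linearly against
#' \eqn{\Sigma + \epsilon I}; the covariance is never inverted explicitly.
#'
#' @param delta numeric vector of in-group minus out-group means.
#' @param sigma covariance matrix of the out-group cells over the same
#'   features.
#' @param epsilon_scale ridge scale: `epsilon = epsilon_scale * mean(diag(sigma))`
#'   (default 1e-6), guarding against fewer out-group cells than features.
#' @return numeric vector `d` (named like `delta`), with the condition number
#'   of the regularised system as attribute `"condition_number"`.
#' @export
mahalanobis_scores <- function(delta, sigma, epsilon_scale = 1e-6) {
  sigma <- as.matrix(sigma)
  stopifnot(length(delta) == nrow(sigma), nrow(sigma) == ncol(sigma))
  eps <- epsilon_scale * mean(diag(sigma))
  if (!is.finite(eps) || eps < 0) eps <- 0
  sreg <- sigma + diag(eps, nrow(sigma))
  kp <- kappa(sreg, exact = TRUE)
  d <- tryCatch(
    drop(solve(sreg, delta * abs(delta))),
    error = function(e) {
      stop(sprintf("regularised covariance system is singular (condition number %.3g)", kp),
           call. = FALSE)
    })
  names(d) <- names(delta)
  structure(d, condition_number = kp)
}

new_feature_ranking <- function(target, features, scores, method,
                                preselect_stat = NULL, lambda = NULL,
                                extra = list()) {
  structure(c(list(target = target, features = features, scores = scores,
                   method = method, preselect_statistic = preselect_stat,
                   lambda = lambda), extra),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %s ranking for '%s': %d features\n",
              x$method, x$target, length(x$features)))
  cat("  head:", paste(utils::head(x$features, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Rank features by the modified Mahalanobis statistic
#'
#' Refines a pre-selected feature set for one target cell type by the
#' covariance-adjusted signed-squared standardised difference (see
#' [mahalanobis_scores()]). The covariance is estimated from the out-group
#' cells on the pre-selected features only. Ranking is by decreasing score
#' (decreasing absolute score with `absolute = TRUE`), ties broken by
#' feature ID.
#'
#' @param Y a labelled [cell_matrix()].
#' @param target_type a label present in `Y`.
#' @param preselected feature IDs (e.g. from [preselect_features()]); default
#'   all features.
#' @param epsilon_scale ridge scale passed to [mahalanobis_scores()].
#' @param absolute rank by `|d|` instead of signed `d`.
#' @return a `feature_ranking` object.
#' @export
rank_features_mahalanobis <- function(Y, target_type,
                                      preselected = rownames(Y$values),
                                      epsilon_scale = 1e-6, absolute = FALSE) {
  g <- group_split(Y, target_type)
  if (length(g$out_idx) < 2) stop("need >= 2 out-group cells", call. = FALSE)
  preselected <- as.character(preselected)
  missing_ft <- setdiff(preselected, rownames(Y$values))
  if (length(missing_ft)) {
    stop("preselected features absent from matrix: ",
         paste(utils::head(missing_ft, 5), collapse = ", "), call. = FALSE)
  }
  sub <- Y$values[preselected, , drop = FALSE]
  delta <- rowMeans(sub[, g$in_idx, drop = FALSE]) -
    rowMeans(sub[, g$out_idx, drop = FALSE])
  sigma <- stats::cov(t(sub[, g$out_idx, drop = FALSE]))
  d <- mahalanobis_scores(delta, sigma, epsilon_scale)
  key <- if (absolute) -abs(d) else -d
  o <- order(key, names(d))
  new_feature_ranking(target_type, names(d)[o], d[o], "mahalanobis",
                      extra = list(epsilon_scale = epsilon_scale,
                                   condition_number = attr(d, "condition_number"),
                                   delta = delta))
}

#' Rank genes by negative-binomial differential expression
#'
#' A two-group test of each gene's upregulation in the target cell type
#' against all other cells pooled. Counts are modelled as negative binomial
#' with library-size offsets; per-gene dispersions are estimated by method of
#' moments and moderated by a trend on abundance (lowess on the
#' mean-normalised count), and a one-sided Wald test compares the two group
#' rates. Genes are ranked by increasing one-sided p-value (in-group higher),
#' ties by the z statistic and then feature ID. A functional equivalent of a
#' standard DE package's gene ranking, not a numerical clone of any.
#'
#' @param Y a labelled [cell_matrix()] of counts.
#' @param target_type a label present in `Y`.
#' @return a `feature_ranking` object; `scores` holds the Wald z statistics
#'   and the element `p_values` the one-sided p-values (both in ranked order).
#' @export
rank_features_de <- function(Y, target_type) {
  g <- group_split(Y, target_type)
  if (length(g$in_idx) < 2 || length(g$out_idx) < 2) {
    stop("both groups need at least 2 cells", call. = FALSE)
  }
  v <- Y$values
  s <- colSums(v)
  if (any(s == 0)) stop("cells with zero total count; filter first", call. = FALSE)
  n <- ncol(v)
  s_in <- s[g$in_idx]; s_out <- s[g$out_idx]
  S_in <- sum(s_in); S_out <- sum(s_out)
  y_in <- rowSums(v[, g$in_idx, drop = FALSE])
  y_out <- rowSums(v[, g$out_idx, drop = FALSE])
  # group rates per unit library size (MLE under Poisson, consistent under NB)
  r_in <- y_in / S_in
  r_out <- y_out / S_out
  # method-of-moments dispersion from residuals around group means
  mu <- outer(r_in, s) ; mu[, g$out_idx] <- outer(r_out, s_out)
  mu[, g$in_idx] <- outer(r_in, s_in)
  resid2 <- (v - mu)^2
  num <- rowSums(resid2) * n / max(1, n - 2) - rowSums(mu)
  den <- rowSums(mu^2)
  phi_raw <- ifelse(den > 0, pmax(0, num / den), 0)
  # moderate by a trend on abundance
  ab <- log((y_in + y_out + 0.5) / (S_in + S_out))
  pos <- den > 0
  phi <- phi_raw
  if (sum(pos) >= 10 && stats::sd(ab[pos]) > 0) {
    tr <- stats::lowess(ab[pos], phi_raw[pos], f = 0.5)
    phi[pos] <- pmax(0, stats::approx(tr$x, tr$y, xout = ab[pos], rule = 2,
                                      ties = mean)$y)
  }
  # continuity-correct zero rates so every statistic is finite
  r_in_c <- pmax(r_in, 0.5 / S_in)
  r_out_c <- pmax(r_out, 0.5 / S_out)
  var_r <- function(r, sv, Sv) (r * Sv + phi * r^2 * sum(sv^2)) / Sv^2
  se2 <- var_r(r_in_c, s_in, S_in) / r_in_c^2 + var_r(r_out_c, s_out, S_out) / r_out_c^2
  z <- (log(r_in_c) - log(r_out_c)) / sqrt(se2)
  p <- stats::pnorm(z, lower.tail = FALSE)
  names(z) <- names(p) <- rownames(v)
  o <- order(p, -z, names(z))
  new_feature_ranking(target_type, names(z)[o], z[o], "de",
                      extra = list(p_values = p[o], dispersion = phi))
}

#' Build a signature matrix from per-type feature rankings
#'
#' The signature feature set is the union of each cell type's `top_n`
#' ranked features; each column of A is the mean profile of that type's
#' cells over the union. The result is invariant to cell order.
#'
#' @param Y a labelled [cell_matrix()].
#' @param rankings named list of `feature_ranking` objects covering every
#'   label of `Y`.
#' @param top_n features taken from the head of each ranking (default 250).
#' @param modality modality recorded on the result (default `"rna_counts"`).
#' @return a [reference_matrix()].
#' @export
build_reference <- function(Y, rankings, top_n = 250, modality = "rna_counts") {
  if (is.null(Y$labels)) stop("cell matrix must carry labels", call. = FALSE)
  types <- sort(unique(Y$labels))
  if (!all(types %in% names(rankings))) {
    stop("rankings must cover every cell type: missing ",
         paste(setdiff(types, names(rankings)), collapse = ", "), call. = FALSE)
  }
  sel <- sort(unique(unlist(lapply(rankings[types], function(r) {
    utils::head(r$features, top_n)
  }))))
  if (length(sel) < length(types)) {
    stop("union of selected features is smaller than the number of cell types",
         call. = FALSE)
  }
  A <- vapply(types, function(tp) {
    rowMeans(Y$values[sel, Y$labels == tp, drop = FALSE])
  }, numeric(length(sel)))
  rownames(A) <- sel
  reference_matrix(A, modality = modality)
}

#' Select discriminative DNA methylation loci from purified profiles
#'
#' Applies three criteria to beta-value profiles of purified cell
#' populations, one epithelial subtype of interest at a time:
#' (1) variance of beta across the non-epithelial lineages below
#' `max_nonepi_var`; (2) absolute difference of at least `min_delta_beta`
#' between the subtype's beta and the mean non-epithelial beta; and, among
#' these candidates, (3) the `quota` loci with the greatest maximum pairwise
#' beta difference between the epithelial subtypes. The signature matrix is
#' the epithelial profiles restricted to the union of the per-subtype
#' selections.
#'
#' @param epi_profiles a [feature_matrix()] (`dname_beta`) with one column
#'   per epithelial subtype.
#' @param nonepi_profiles a [feature_matrix()] (`dname_beta`) with one column
#'   per non-epithelial lineage (at least 2).
#' @param max_nonepi_var criterion (1) threshold (default 0.001).
#' @param min_delta_beta criterion (2) threshold (default 0.5).
#' @param quota loci retained per subtype by criterion (3) (default 20).
#' @return a [reference_matrix()] (`dname_beta`) with the epithelial subtypes
#'   as columns; the per-subtype selections are attached as attribute
#'   `"selected_by_subtype"`.
#' @export
select_dname_loci <- function(epi_profiles, nonepi_profiles,
                              max_nonepi_var = 0.001, min_delta_beta = 0.5,
                              quota = 20) {
  stopifnot(inherits(epi_profiles, "feature_matrix"),
            inherits(nonepi_profiles, "feature_matrix"),
            epi_profiles$modality == "dname_beta",
            nonepi_profiles$modality == "dname_beta",
            max_nonepi_var > 0, min_delta_beta > 0, quota >= 1)
  if (ncol(nonepi_profiles$values) < 2) {
    stop("need >= 2 non-epithelial lineages for the variance criterion", call. = FALSE)
  }
  shared <- intersect(rownames(epi_profiles$values), rownames(nonepi_profiles$values))
  if (!length(shared)) stop("no shared loci between profiles", call. = FALSE)
  E <- epi_profiles$values[shared, , drop = FALSE]
  N <- nonepi_profiles$values[shared, , drop = FALSE]
  if (anyNA(E) || anyNA(N)) stop("profiles must be complete on shared loci", call. = FALSE)
  v_nonepi <- apply(N, 1, stats::var)
  mean_nonepi <- rowMeans(N)
  # criterion (3): greatest max-pairwise |delta beta| between epithelial subtypes
  spread <- apply(E, 1, function(b) max(b) - min(b))
  picks <- list()
  for (sub in colnames(E)) {
    cand <- shared[v_nonepi < max_nonepi_var &
                     abs(E[, sub] - mean_nonepi) >= min_delta_beta]
    if (!length(cand)) {
      stop("no candidate loci satisfy criteria (1)-(2) for subtype '", sub, "'",
           call. = FALSE)
    }
    o <- order(-spread[cand], cand)
    picks[[sub]] <- cand[o][seq_len(min(quota, length(cand)))]
  }
  sel <- sort(unique(unlist(picks)))
  A <- reference_matrix(E[sel, , drop = FALSE], modality = "dname_beta")
  attr(A, "selected_by_subtype") <- picks
  A
}
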
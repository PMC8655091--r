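# Data-cleaning filters applied upstream of signature construction and
# deconvolution: detection-p coverage filtering of array probes, feature-wise
# kNN imputation, single-cell library/transcript filters, and conversion of
# bisulphite read counts to beta values with a read-depth floor.

#' Bisulphite read counts per locus and sample
#'
#' @param methylated,unmethylated non-negative integer matrices of identical
#'   shape (loci x samples) counting mapped methylated / unmethylated reads.
#' @return an object of class `bisulphite_counts`.
#' @export
bisulphite_counts <- function(methylated, unmethylated) {
  methylated <- as.matrix(methylated)
  unmethylated <- as.matrix(unmethylated)
  if (!identical(dim(methylated), dim(unmethylated))) {
    stop("count matrices must have identical shape", call. = FALSE)
  }
  for (m in list(methylated, unmethylated)) {
    if (anyNA(m) || min(m) < 0 || any(m != round(m))) {
      stop("read counts must be non-negative integers", call. = FALSE)
    }
  }
  if (is.null(rownames(methylated))) {
    rownames(methylated) <- rownames(unmethylated) <- paste0("locus", seq_len(nrow(methylated)))
  }
  if (is.null(colnames(methylated))) {
    colnames(methylated) <- colnames(unmethylated) <- paste0("s", seq_len(ncol(methylated)))
  }
  dimnames(unmethylated) <- dimnames(methylated)
  structure(list(methylated = methylated, unmethylated = unmethylated),
            class = "bisulphite_counts")
}

#' Filter array probes by detection coverage
#'
#' Removes probes detected (detection p-value at most `p_cut`) in fewer than
#' `min_coverage` of samples, and marks the surviving entries that failed
#' detection as missing so they can be imputed.
#'
#' @param X a [feature_matrix()].
#' @param D numeric matrix of detection p-values with the same shape and
#'   dimnames as `X`.
#' @param min_coverage minimum fraction of samples in which a probe must be
#'   detected to be retained (default 0.95; the boundary is kept).
#' @param p_cut detection p-value threshold (default 0.05).
#' @return a filtered [feature_matrix()] with failed entries set `NA`.
#' @export
filter_probes_by_coverage <- function(X, D, min_coverage = 0.95, p_cut = 0.05) {
  stopifnot(inherits(X, "feature_matrix"))
  D <- as.matrix(D)
  if (!identical(dim(D), dim(X$values))) {
    stop("detection matrix shape does not match the feature matrix", call. = FALSE)
  }
  if (!is.null(rownames(D)) && !identical(rownames(D), rownames(X$values))) {
    stop("detection matrix feature IDs do not match", call. = FALSE)
  }
  if (anyNA(D) || min(D) < 0 || max(D) > 1) {
    stop("detection p-values must lie in [0,1]", call. = FALSE)
  }
  detected <- D <= p_cut
  keep <- rowMeans(detected) >= min_coverage
  v <- X$values[keep, , drop = FALSE]
  v[!detected[keep, , drop = FALSE]] <- NA_real_
  log_msg(sprintf("coverage filter: kept %d/%d probes, marked %d entries missing",
                  sum(keep), nrow(X$values), sum(is.na(v))))
  feature_matrix(v, X$modality)
}

#' k-nearest-neighbour imputation of missing entries
#'
#' Feature-wise kNN in the style used for methylation arrays: for a missing
#' entry (feature i, sample j), the k features nearest to i — by mean squared
#' difference over the samples where both features are observed — among those
#' observed at sample j supply the imputed value as their mean at j. Distance
#' ties are broken by feature ID so the result is deterministic. Observed
#' entries are never changed.
#'
#' @param X a [feature_matrix()], possibly with `NA` entries.
#' @param k number of neighbours (default 5).
#' @return a complete [feature_matrix()].
#' @export
knn_impute <- function(X, k = 5) {
  stopifnot(inherits(X, "feature_matrix"), k >= 1)
  v <- X$values
  if (!anyNA(v)) return(X)
  obs <- !is.na(v)
  dead <- rownames(v)[rowSums(obs) == 0]
  if (length(dead)) {
    stop("features with no observed values cannot be imputed: ",
         paste(dead, collapse = ", "), call. = FALSE)
  }
  out <- v
  miss_feats <- which(rowSums(!obs) > 0)
  ord_ids <- order(rownames(v))  # lexicographic tie-break order
  for (i in miss_feats) {
    for (j in which(!obs[i, ])) {
      cand <- which(obs[, j])
      cand <- setdiff(cand, i)
      if (length(cand) < k) {
        stop(sprintf("fewer than k=%d candidate neighbour features observed at sample '%s'",
                     k, colnames(v)[j]), call. = FALSE)
      }
      both <- obs[rep(i, length(cand)), , drop = FALSE] & obs[cand, , drop = FALSE]
      d <- vapply(seq_along(cand), function(ci) {
        sh <- both[ci, ]
        if (!any(sh)) return(Inf)
        mean((v[i, sh] - v[cand[ci], sh])^2)
      }, numeric(1))
      o <- order(d, rownames(v)[cand])
      nb <- cand[o][seq_len(k)]
      out[i, j] <- mean(v[nb, j])
    }
  }
  feature_matrix(out, X$modality)
}

#' Filter single-cell libraries and low-prevalence transcripts
#'
#' Cells with total count below `min_reads` are removed first; then
#' transcripts expressed (count > 0) in fewer than `min_cells` of the
#' surviving cells are removed. Defaults match standard droplet QC for large
#' atlases (at least 250 reads per library; transcripts seen in at least 1000
#' cells); for small matrices pass smaller thresholds.
#'
#' @param Y a [cell_matrix()] of counts.
#' @param min_reads minimum library size (default 250; the boundary is kept).
#' @param min_cells minimum number of expressing cells (default 1000).
#' @return a filtered [cell_matrix()] (labels subset accordingly).
#' @export
filter_sc_libraries <- function(Y, min_reads = 250, min_cells = 1000) {
  stopifnot(inherits(Y, "cell_matrix"))
  keep_cells <- colSums(Y$values) >= min_reads
  if (!any(keep_cells)) stop("all cells removed by the library-size filter", call. = FALSE)
  v <- Y$values[, keep_cells, drop = FALSE]
  keep_tx <- rowSums(v > 0) >= min_cells
  v <- v[keep_tx, , drop = FALSE]
  log_msg(sprintf("library filter: kept %d/%d cells, %d/%d transcripts",
                  sum(keep_cells), ncol(Y$values), sum(keep_tx), nrow(Y$values)))
  lab <- if (is.null(Y$labels)) NULL else Y$labels[keep_cells]
  # labels are carried through without re-imposing the >=2-cells-per-type
  # invariant: filtering may legitimately deplete a type, and the invariant
  # belongs to reference construction, not QC
  structure(list(values = v, labels = lab), class = "cell_matrix")
}

#' Beta values from bisulphite read counts
#'
#' Converts methylated/unmethylated read counts to methylation rates
#' beta = methylated / (methylated + unmethylated), keeping only loci whose
#' total mapped read depth is at least `min_total` in every sample. The
#' default depth of 20 bounds the granularity of the methylation rate at
#' 0.05. Loci failing the depth floor in any sample are dropped entirely so
#' that downstream reference profiles are complete.
#'
#' @param C a [bisulphite_counts()] object.
#' @param min_total minimum total read depth per locus and sample (default 20).
#' @return a [feature_matrix()] with modality `"dname_beta"`.
#' @export
beta_from_bisulphite <- function(C, min_total = 20) {
  stopifnot(inherits(C, "bisulphite_counts"))
  total <- C$methylated + C$unmethylated
  keep <- apply(total >= min_total, 1, all)
  if (!any(keep)) stop("no locus meets the read-depth floor in all samples", call. = FALSE)
  beta <- C$methylated[keep, , drop = FALSE] / total[keep, , drop = FALSE]
  feature_matrix(beta, "dname_beta")
}
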
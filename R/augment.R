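# Quantile-matching augmentation: re-express a purified bulk reference
# profile (e.g. stromal or adipose RNA-seq) on the empirical distribution of
# a randomly sampled single-cell library, so the augmented reference shares
# the sparsity and scale of the single-cell data it is deconvolved alongside.

#' Map a reference profile onto a single-cell library's quantiles
#'
#' Computes \eqn{\tilde x_i = \hat F_b^{-1}[\hat F_{ref}(x^{ref}_i)]} with a
#' right-continuous empirical CDF and the type-1 (smallest-value) inverse:
#' each reference value is replaced by the single-cell value at its own
#' quantile. Ranks of the reference are preserved exactly; ties in the
#' reference map to equal outputs; a constant reference maps to `max(sc)`
#' (quantile 1 under the right-continuous convention).
#'
#' @param x_ref numeric reference vector over p genes.
#' @param sc_library numeric vector over the same p genes.
#' @return mapped vector, a sub-multiset of `sc_library`'s values.
#' @export
quantile_map <- function(x_ref, sc_library) {
  if (length(x_ref) != length(sc_library)) {
    stop("reference and single-cell vectors must have equal length", call. = FALSE)
  }
  if (anyNA(x_ref) || anyNA(sc_library)) stop("missing values not allowed", call. = FALSE)
  p <- length(x_ref)
  r <- rank(x_ref, ties.method = "max")        # F_ref(x_i) = r_i / p
  out <- sort(sc_library)[r]                   # type-1 inverse at quantile r/p
  names(out) <- names(x_ref)
  out
}

#' Augment bulk references with quantile-matched synthetic libraries
#'
#' For each of `B` draws, one single cell is sampled uniformly (with
#' replacement, seeded) and every bulk reference profile is re-expressed on
#' that cell's empirical distribution via [quantile_map()]. Gene sets are
#' intersected first.
#'
#' @param sc a [cell_matrix()] of single-cell counts.
#' @param bulk_refs a [feature_matrix()] of purified bulk reference profiles
#'   (one column per reference).
#' @param B number of synthetic libraries per reference (default 100).
#' @param seed RNG seed.
#' @return an object of class `augmented_set`: `libraries` (named list of
#'   p x B matrices, one per reference), `sampled_cells` (cell ID per draw),
#'   `zero_fraction` (per reference and draw), `seed`.
#' @export
augment_reference_set <- function(sc, bulk_refs, B = 100, seed = 1) {
  stopifnot(inherits(sc, "cell_matrix"), inherits(bulk_refs, "feature_matrix"),
            B >= 1)
  genes <- intersect(rownames(sc$values), rownames(bulk_refs$values))
  if (!length(genes)) stop("empty gene intersection", call. = FALSE)
  scv <- sc$values[genes, , drop = FALSE]
  refs <- bulk_refs$values[genes, , drop = FALSE]
  if (anyNA(refs)) stop("bulk references must be complete on shared genes", call. = FALSE)
  set.seed(seed)
  cells <- sample.int(ncol(scv), B, replace = TRUE)
  libs <- lapply(colnames(refs), function(rn) {
    out <- vapply(cells, function(ci) quantile_map(refs[, rn], scv[, ci]),
                  numeric(length(genes)))
    dimnames(out) <- list(genes, paste0(rn, "_b", seq_len(B)))
    out
  })
  names(libs) <- colnames(refs)
  zf <- vapply(libs, function(m) colMeans(m == 0), numeric(B))
  log_msg(sprintf("augmented %d reference(s) with B=%d libraries; mean zero fraction %.2f",
                  length(libs), B, mean(zf)))
  structure(list(libraries = libs,
                 sampled_cells = colnames(scv)[cells],
                 zero_fraction = zf, seed = seed),
            class = "augmented_set")
}

#' @export
print.augmented_set <- function(x, ...) {
  cat(sprintf("<augmented_set> %d reference(s) x %d libraries, %d genes\n",
              length(x$libraries), length(x$sampled_cells),
              nrow(x$libraries[[1]])))
  invisible(x)
}
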
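#' @keywords internal
#' @importFrom mclust Mclust mclustBIC
"_PACKAGE"

MODALITIES <- c("dname_beta", "rna_counts", "rna_log")

log_msg <- function(...) {
  if (isTRUE(getOption("epistratify.verbose", FALSE))) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  }
  invisible(NULL)
}

check_ids <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(ids == "")) {
    stop(what, " must be non-empty strings", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate ", what, ": ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(ids)
}

check_modality_values <- function(values, modality, what = "matrix") {
  obs <- values[!is.na(values)]
  if (any(!is.finite(obs))) stop(what, " contains non-finite values", call. = FALSE)
  if (modality == "dname_beta" && length(obs) && (min(obs) < 0 || max(obs) > 1)) {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)[1, ]
    stop(sprintf("beta value %.4g outside [0,1] at feature '%s', sample '%s'",
                 values[bad[1], bad[2]], rownames(values)[bad[1]],
                 colnames(values)[bad[2]]), call. = FALSE)
  }
  if (modality == "rna_counts" && length(obs) && min(obs) < 0) {
    stop("negative values not allowed under rna_counts", call. = FALSE)
  }
  invisible(values)
}

#' Bulk feature-by-sample matrix
#'
#' Container for the bulk observations \eqn{X} of the deconvolution model
#' \eqn{X = AW + \epsilon}: one row per genomic feature (CpG locus, gene or
#' transcript) and one column per bulk-tissue sample. DNA methylation data are
#' stored as beta values (the methylation rate, i.e. the fraction of DNA
#' strands methylated at a locus) and validated to lie in \[0,1\]; RNA data as
#' non-negative counts or on a log scale. Missing entries are `NA`.
#'
#' @param values numeric matrix, features in rows, samples in columns. Row and
#'   column names are used as feature/sample identifiers when `feature_ids` /
#'   `sample_ids` are not given.
#' @param modality one of `"dname_beta"`, `"rna_counts"`, `"rna_log"`.
#' @param feature_ids,sample_ids optional identifier vectors (unique,
#'   non-empty).
#' @return an object of class `feature_matrix` with elements `values`
#'   (named numeric matrix) and `modality`.
#' @export
feature_matrix <- function(values, modality, feature_ids = rownames(values),
                           sample_ids = colnames(values)) {
  modality <- match.arg(modality, MODALITIES)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  check_ids(as.character(feature_ids), "feature IDs")
  check_ids(as.character(sample_ids), "sample IDs")
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("ID lengths do not match matrix dimensions", call. = FALSE)
  }
  dimnames(values) <- list(as.character(feature_ids), as.character(sample_ids))
  check_modality_values(values, modality)
  structure(list(values = values, modality = modality), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d samples, modality %s, %d missing\n",
              nrow(x$values), ncol(x$values), x$modality, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Cell-type signature (reference) matrix
#'
#' Container for the reference matrix \eqn{A} of \eqn{X = AW + \epsilon}: the
#' expected value of each selected discriminative feature in each pure cell
#' type. Validated to have at least as many features as cell types, distinct
#' columns and full column rank; the condition number is recorded because it
#' bounds how well proportions can be separated.
#'
#' @param values numeric matrix, selected features in rows, cell types in
#'   columns.
#' @param modality one of `"dname_beta"`, `"rna_counts"`, `"rna_log"`.
#' @param feature_ids,cell_type_names optional identifier vectors.
#' @param check_rank if `TRUE` (default) fail when the matrix is column
#'   rank-deficient; set `FALSE` only for deliberately degenerate study
#'   objects (a warning is still emitted).
#' @return an object of class `reference_matrix` with elements `values`,
#'   `modality` and `condition_number`.
#' @export
reference_matrix <- function(values, modality, feature_ids = rownames(values),
                             cell_type_names = colnames(values),
                             check_rank = TRUE) {
  modality <- match.arg(modality, MODALITIES)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  if (is.null(cell_type_names)) cell_type_names <- paste0("type", seq_len(ncol(values)))
  check_ids(as.character(feature_ids), "feature IDs")
  check_ids(as.character(cell_type_names), "cell type names")
  dimnames(values) <- list(as.character(feature_ids), as.character(cell_type_names))
  if (anyNA(values)) stop("reference matrix must be complete (no NA)", call. = FALSE)
  check_modality_values(values, modality, "reference matrix")
  if (nrow(values) < ncol(values)) {
    stop("reference matrix needs at least as many features as cell types", call. = FALSE)
  }
  if (ncol(values) > 1 && any(duplicated(t(values)))) {
    stop("reference matrix columns must be distinct", call. = FALSE)
  }
  r <- qr(values)$rank
  kp <- kappa(values, exact = TRUE)
  if (r < ncol(values)) {
    msg <- sprintf("reference matrix is column rank-deficient (rank %d < %d cell types)",
                   r, ncol(values))
    if (check_rank) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  structure(list(values = values, modality = modality, condition_number = kp),
            class = "reference_matrix")
}

#' @export
print.reference_matrix <- function(x, ...) {
  cat(sprintf("<reference_matrix> %d features x %d cell types (%s), condition number %.3g\n",
              nrow(x$values), ncol(x$values), x$modality, x$condition_number))
  cat("  cell types:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.reference_matrix <- function(x) dim(x$values)

#' Estimated mixing-proportion matrix
#'
#' Container for the mixing matrix \eqn{W}: one row per cell type, one column
#' per bulk sample, entries the estimated proportions. Entries flagged
#' `inestimable` (robust-fit non-convergence or complete zeroing by the
#' adaptive noise threshold) carry `NA` values; every fully estimable column
#' is non-negative and sums to 1 within `1e-8`.
#'
#' @param values numeric matrix, cell types in rows, samples in columns (`NA`
#'   at flagged entries).
#' @param inestimable logical matrix of the same shape (default: no flags).
#' @param cell_type_names,sample_ids optional identifier vectors.
#' @return an object of class `mixing_matrix`.
#' @export
mixing_matrix <- function(values, inestimable = NULL,
                          cell_type_names = rownames(values),
                          sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(inestimable)) inestimable <- matrix(FALSE, nrow(values), ncol(values))
  inestimable <- as.matrix(inestimable)
  if (!identical(dim(values), dim(inestimable))) {
    stop("inestimable flags must match the proportion matrix shape", call. = FALSE)
  }
  if (is.null(cell_type_names)) cell_type_names <- paste0("type", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  check_ids(as.character(cell_type_names), "cell type names")
  check_ids(as.character(sample_ids), "sample IDs")
  dimnames(values) <- list(as.character(cell_type_names), as.character(sample_ids))
  dimnames(inestimable) <- dimnames(values)
  ok <- !inestimable
  v <- values[ok]
  if (any(is.na(v))) stop("non-flagged proportions must not be NA", call. = FALSE)
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    stop("proportions must lie in [0,1]", call. = FALSE)
  }
  clean <- which(colSums(inestimable) == 0)
  if (length(clean)) {
    s <- colSums(values[, clean, drop = FALSE])
    if (any(abs(s - 1) > 1e-8)) {
      stop("estimable proportion columns must sum to 1 within 1e-8", call. = FALSE)
    }
  }
  structure(list(values = values, inestimable = inestimable),
            class = "mixing_matrix")
}

#' @export
print.mixing_matrix <- function(x, ...) {
  pct <- 100 * mean(x$inestimable)
  cat(sprintf("<mixing_matrix> %d cell types x %d samples, %.1f%% inestimable\n",
              nrow(x$values), ncol(x$values), pct))
  print(utils::head(t(x$values), 5))
  invisible(x)
}

#' @export
dim.mixing_matrix <- function(x) dim(x$values)

#' Labelled single-cell matrix
#'
#' Container for a features-by-cells single-cell matrix \eqn{Y}, optionally
#' carrying one cell-type label per cell (labels may be absent before
#' clustering). When labels are present there must be at least two types and
#' at least two cells per type, the minimum for the covariance estimates used
#' in signature construction.
#'
#' @param values non-negative numeric matrix, features in rows, cells in
#'   columns.
#' @param labels optional character vector of per-cell type labels.
#' @param feature_ids,cell_ids optional identifier vectors.
#' @return an object of class `cell_matrix` with elements `values` and
#'   `labels` (`NULL` if unlabelled).
#' @export
cell_matrix <- function(values, labels = NULL, feature_ids = rownames(values),
                        cell_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) feature_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(ncol(values)))
  check_ids(as.character(feature_ids), "feature IDs")
  check_ids(as.character(cell_ids), "cell IDs")
  dimnames(values) <- list(as.character(feature_ids), as.character(cell_ids))
  if (anyNA(values) || min(values) < 0) {
    stop("single-cell matrix must be complete and non-negative", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != ncol(values)) {
      stop("need one label per cell", call. = FALSE)
    }
    tab <- table(labels)
    if (length(tab) < 2) stop("labels must span at least 2 cell types", call. = FALSE)
    if (any(tab < 2)) {
      stop("each labelled cell type needs at least 2 cells (covariance estimation): ",
           paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
    }
    names(labels) <- colnames(values)
  }
  structure(list(values = values, labels = labels), class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d features x %d cells%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) " (unlabelled)" else
                paste0(", types: ", paste(names(table(x$labels)), collapse = ", "))))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

#' Marker gene sets
#'
#' A named collection of marker-gene identifier lists, one list per cell type,
#' used to name clusters by their mean log marker expression.
#'
#' @param sets named list of non-empty character vectors.
#' @return an object of class `marker_sets`.
#' @export
marker_sets <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("marker sets must be a named list", call. = FALSE)
  }
  check_ids(names(sets), "marker set names")
  sets <- lapply(sets, as.character)
  if (any(vapply(sets, length, 1L) == 0)) {
    stop("every marker set must be non-empty", call. = FALSE)
  }
  structure(sets, class = "marker_sets")
}

#' @export
print.marker_sets <- function(x, ...) {
  cat("<marker_sets>\n")
  for (nm in names(x)) cat(sprintf("  %s: %d genes\n", nm, length(x[[nm]])))
  invisible(x)
}
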
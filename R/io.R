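# Text I/O: dense matrices as TSV/CSV (tab default, comma autodetect),
# sparse single-cell data as MatrixMarket triplets with sidecar ID lists,
# marker sets as two-column TSV. All files UTF-8; missing values as "NA".

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

read_delim_matrix <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

write_delim_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a bulk feature matrix from TSV/CSV
#'
#' Expects a header row of sample IDs and a first column of feature IDs;
#' the delimiter (tab or comma) is autodetected. Values are validated against
#' the declared modality (beta values in \[0,1\], counts non-negative);
#' duplicate identifiers and out-of-range values are hard errors.
#'
#' @param path path to a delimited text file.
#' @param modality one of `"dname_beta"`, `"rna_counts"`, `"rna_log"`.
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(path, modality) {
  feature_matrix(read_delim_matrix(path), modality = modality)
}

#' Write a bulk feature matrix to TSV
#'
#' @param X a [feature_matrix()].
#' @param path output path. Missing entries are written as `NA`.
#' @return the path, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  stopifnot(inherits(X, "feature_matrix"))
  write_delim_matrix(X$values, path)
}

#' Read a signature matrix from TSV/CSV
#'
#' @param path delimited file: feature IDs in the first column, cell types in
#'   the header.
#' @inheritParams read_feature_matrix
#' @return a [reference_matrix()]; the condition number is computed at load.
#' @export
read_reference_matrix <- function(path, modality) {
  reference_matrix(read_delim_matrix(path), modality = modality)
}

#' Write a signature matrix to TSV
#'
#' @param A a [reference_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_reference_matrix <- function(A, path) {
  stopifnot(inherits(A, "reference_matrix"))
  write_delim_matrix(A$values, path)
}

#' Write estimated proportions to TSV
#'
#' Cell types are rows, samples are columns; entries flagged inestimable are
#' written as the token `NA`. A write/read round trip reproduces every
#' estimable value to 1e-12.
#'
#' @param W a [mixing_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mixing_matrix <- function(W, path) {
  stopifnot(inherits(W, "mixing_matrix"))
  v <- W$values
  v[W$inestimable] <- NA_real_
  op <- options(digits = 17)
  on.exit(options(op))
  write_delim_matrix(v, path, id_col = "cell_type")
  invisible(path)
}

#' Read estimated proportions from TSV
#'
#' @param path a file written by [write_mixing_matrix()]; `NA` tokens become
#'   inestimable flags.
#' @return a [mixing_matrix()].
#' @export
read_mixing_matrix <- function(path) {
  m <- read_delim_matrix(path)
  mixing_matrix(m, inestimable = is.na(m))
}

#' Read a sparse single-cell matrix (MatrixMarket triplet)
#'
#' Reads an MTX file together with sidecar feature and barcode lists (one ID
#' per line, or the first column of a multi-column TSV) and returns a dense
#' labelled cell matrix; entries absent from the triplet list are zeros.
#'
#' @param mtx path to the MatrixMarket file (features x cells).
#' @param features,barcodes paths to the sidecar ID lists.
#' @param labels optional: path to a per-cell label file aligned with
#'   `barcodes` (single column or `barcode<TAB>label`), or a character vector.
#' @return a [cell_matrix()].
#' @export
read_cell_matrix_mtx <- function(mtx, features, barcodes, labels = NULL) {
  m <- as.matrix(Matrix::readMM(mtx))
  read_ids <- function(p) {
    x <- utils::read.table(p, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                           quote = "", comment.char = "", fileEncoding = "UTF-8")
    as.character(x[[1]])
  }
  fid <- read_ids(features)
  cid <- read_ids(barcodes)
  if (length(fid) != nrow(m) || length(cid) != ncol(m)) {
    stop("sidecar ID lists do not match the MTX dimensions", call. = FALSE)
  }
  lab <- NULL
  if (!is.null(labels)) {
    if (length(labels) == 1 && file.exists(labels)) {
      x <- utils::read.table(labels, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             fileEncoding = "UTF-8")
      lab <- as.character(x[[ncol(x)]])
    } else {
      lab <- as.character(labels)
    }
  }
  cell_matrix(m, labels = lab, feature_ids = fid, cell_ids = cid)
}

#' Read a dense single-cell matrix from TSV/CSV
#'
#' @param path delimited file with feature IDs in the first column.
#' @param labels optional label file or character vector (see
#'   [read_cell_matrix_mtx()]).
#' @return a [cell_matrix()].
#' @export
read_cell_matrix <- function(path, labels = NULL) {
  m <- read_delim_matrix(path)
  lab <- NULL
  if (!is.null(labels)) {
    if (length(labels) == 1 && file.exists(labels)) {
      x <- utils::read.table(labels, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             fileEncoding = "UTF-8")
      lab <- as.character(x[[ncol(x)]])
    } else {
      lab <- as.character(labels)
    }
  }
  cell_matrix(m, labels = lab)
}

#' Write a single-cell matrix as MatrixMarket triplets
#'
#' Writes `counts.mtx`, `features.tsv`, `barcodes.tsv` (and `labels.tsv` when
#' labels are present) under a directory.
#'
#' @param Y a [cell_matrix()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cell_matrix_mtx <- function(Y, dir) {
  stopifnot(inherits(Y, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(Y$values, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(Y$values), file.path(dir, "features.tsv"))
  writeLines(colnames(Y$values), file.path(dir, "barcodes.tsv"))
  if (!is.null(Y$labels)) writeLines(unname(Y$labels), file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' Read marker sets from two-column TSV
#'
#' @param path TSV with columns `cell_type`, `gene` (header optional).
#' @return a [marker_sets()] object.
#' @export
read_marker_sets <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  if (identical(tolower(as.character(df[1, 1])), "cell_type")) df <- df[-1, , drop = FALSE]
  marker_sets(split(as.character(df[[2]]), as.character(df[[1]])))
}
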
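# The RLM-pseudo-inverse estimator of mixing proportions.
#
# Model: X = A W + e, with X the bulk observations (p' features x n samples),
# A the cell-type signature matrix and W the column-stochastic proportions.
# Each sample column is fitted independently by robust (Huber IRLS) linear
# regression of x on A without intercept; small negative coefficients are
# treated as noise by an adaptive threshold (anything as small in magnitude
# as the most negative coefficient is zeroed) and the remainder renormalised
# to sum to 1. Samples whose fit does not converge, or whose coefficients are
# entirely zeroed, are flagged inestimable.

align_features <- function(A, X, min_overlap = 0.8) {
  shared <- intersect(rownames(A$values), rownames(X$values))
  if (!length(shared)) stop("zero feature overlap between reference and bulk matrix",
                            call. = FALSE)
  frac <- length(shared) / nrow(A$values)
  if (frac < min_overlap) {
    warning(sprintf("only %.0f%% of reference features found in the bulk matrix",
                    100 * frac), call. = FALSE)
  }
  shared
}

#' Robust linear fit of one bulk sample against a signature matrix
#'
#' Fits `x ~ A` without intercept by iteratively reweighted least squares
#' with Huber weighting (tuning constant 1.345, MAD scale, at most `maxit`
#' iterations) and returns the raw coefficients, which may be negative. The
#' features of `x` are intersected with the rows of `A` (a warning is issued
#' if under 80% of the reference features survive).
#'
#' @param A a [reference_matrix()].
#' @param x named numeric vector: one bulk sample over (a superset of) the
#'   reference features.
#' @param maxit maximum IRLS iterations (default 400).
#' @return an object of class `robust_fit`: `coefficients`, `converged`,
#'   `iterations`, `scale`.
#' @export
rlm_fit <- function(A, x, maxit = 400) {
  stopifnot(inherits(A, "reference_matrix"))
  if (is.null(names(x))) {
    if (length(x) != nrow(A$values)) stop("unnamed x must match A's rows", call. = FALSE)
    names(x) <- rownames(A$values)
  }
  Xf <- feature_matrix(matrix(x, ncol = 1, dimnames = list(names(x), "s1")),
                       modality = A$modality)
  shared <- align_features(A, Xf)
  Av <- A$values[shared, , drop = FALSE]
  if (nrow(Av) < ncol(Av)) stop("fewer overlapping features than cell types", call. = FALSE)
  qrA <- qr(Av)
  if (qrA$rank < ncol(Av)) {
    stop("reference matrix is rank-deficient on the overlapping features", call. = FALSE)
  }
  # an (almost) exact fit degenerates the MAD scale estimate of the IRLS;
  # the least-squares solution is then already the robust solution
  ols <- qr.coef(qrA, x[shared])
  res <- x[shared] - drop(Av %*% ols)
  if (stats::mad(res) <= 1e-10 * max(1, stats::mad(x[shared]))) {
    names(ols) <- colnames(Av)
    return(structure(list(coefficients = ols, converged = TRUE,
                          iterations = 0L, scale = 0),
                     class = "robust_fit"))
  }
  fit <- withCallingHandlers(
    MASS::rlm(Av, x[shared], psi = MASS::psi.huber, k = 1.345,
              scale.est = "MAD", maxit = maxit, acc = 1e-8),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  names(co) <- colnames(Av)
  structure(list(coefficients = co,
                 converged = isTRUE(fit$converged),
                 iterations = length(fit$conv),
                 scale = fit$s),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> %sconverged in %d iterations, scale %.4g\n",
              if (x$converged) "" else "NOT ", x$iterations, x$scale))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Adaptive noise threshold on raw coefficients
#'
#' Small negative coefficients from the robust fit are assumed to be noise.
#' If the most negative coefficient has magnitude `m`, every coefficient
#' whose magnitude is at most `m` is set to zero — all negatives, and any
#' positives no larger than the noise floor. Vectors with no negative entry
#' are returned unchanged. With `most_negative_only = TRUE` only negative
#' entries are zeroed (the stricter alternative reading of the rule).
#'
#' @param w_raw numeric coefficient vector.
#' @param most_negative_only zero only the negative entries (default `FALSE`).
#' @return thresholded vector, never containing negatives.
#' @export
adaptive_noise_threshold <- function(w_raw, most_negative_only = FALSE) {
  if (!length(w_raw) || min(w_raw) >= 0) return(w_raw)
  if (most_negative_only) {
    w_raw[w_raw < 0] <- 0
    return(w_raw)
  }
  m <- abs(min(w_raw))
  w_raw[abs(w_raw) <= m] <- 0
  w_raw
}

#' Normalise non-negative coefficients to proportions
#'
#' Divides by the vector sum so the result sums to 1 within 1e-12. An
#' all-zero input cannot be normalised: it is returned unchanged with
#' attribute `inestimable = TRUE`.
#'
#' @param w non-negative numeric vector.
#' @return proportion vector, or the zero vector flagged inestimable.
#' @export
normalize_proportions <- function(w) {
  if (any(w < 0)) stop("coefficients must be non-negative before normalisation",
                       call. = FALSE)
  s <- sum(w)
  if (s == 0) return(structure(w, inestimable = TRUE))
  w / s
}

#' Estimate cell-type proportions by RLM-pseudo-inverse deconvolution
#'
#' The package's central fitting function. For every sample column of `X`,
#' the pipeline [rlm_fit()] then [adaptive_noise_threshold()] then
#' [normalize_proportions()] produces a column of the mixing matrix W;
#' columns whose robust fit fails to converge or whose coefficients are
#' entirely zeroed are flagged inestimable and reported as `NA`.
#'
#' @param A a [reference_matrix()].
#' @param X a [feature_matrix()] of bulk samples with matching modality.
#' @param maxit maximum IRLS iterations per sample (default 400).
#' @param most_negative_only alternative threshold reading, see
#'   [adaptive_noise_threshold()].
#' @return an object of class `rlmpi_fit` with elements `proportions`
#'   (a [mixing_matrix()]), `raw_coefficients`, `converged`, `inestimable`
#'   (per-sample flags), `reference`, `features_used` and `call`. Methods:
#'   `print`, `summary`, `coef`, `fitted`, `residuals`, `plot`.
#' @examples
#' A <- make_synthetic_reference(p = 58, k = 3, seed = 1)
#' sim <- simulate_mixtures(A, n = 10, seed = 2)
#' fit <- deconvolve(A, sim$X)
#' coef(fit)[, 1:3]
#' @export
deconvolve <- function(A, X, maxit = 400, most_negative_only = FALSE) {
  stopifnot(inherits(A, "reference_matrix"), inherits(X, "feature_matrix"))
  if (A$modality != X$modality) {
    stop("reference and bulk modality differ (", A$modality, " vs ", X$modality, ")",
         call. = FALSE)
  }
  shared <- align_features(A, X)
  Av <- A$values[shared, , drop = FALSE]
  Ares <- reference_matrix(Av, A$modality)
  k <- ncol(Av); n <- ncol(X$values)
  W <- matrix(NA_real_, k, n, dimnames = list(colnames(Av), colnames(X$values)))
  raw <- W
  converged <- logical(n)
  inest <- logical(n)
  for (j in seq_len(n)) {
    f <- rlm_fit(Ares, X$values[shared, j], maxit = maxit)
    raw[, j] <- f$coefficients
    converged[j] <- f$converged
    w <- normalize_proportions(
      adaptive_noise_threshold(f$coefficients, most_negative_only))
    if (!f$converged || isTRUE(attr(w, "inestimable"))) {
      inest[j] <- TRUE
    } else {
      W[, j] <- w
    }
  }
  flags <- matrix(rep(inest, each = k), k, n, dimnames = dimnames(W))
  log_msg(sprintf("deconvolved %d samples on %d features: %.1f%% inestimable",
                  n, length(shared), 100 * mean(inest)))
  structure(list(proportions = mixing_matrix(W, inestimable = flags),
                 raw_coefficients = raw,
                 converged = converged,
                 inestimable = inest,
                 reference = reference_matrix(Av, A$modality),
                 features_used = shared,
                 bulk = X$values[shared, , drop = FALSE],
                 call = match.call()),
            class = "rlmpi_fit")
}

#' @export
print.rlmpi_fit <- function(x, ...) {
  cat("RLM-pseudo-inverse deconvolution\n")
  cat(sprintf("  %d cell types, %d samples, %d signature features\n",
              nrow(x$proportions$values), ncol(x$proportions$values),
              length(x$features_used)))
  cat(sprintf("  inestimable samples: %d (%.1f%%)\n",
              sum(x$inestimable), 100 * mean(x$inestimable)))
  invisible(x)
}

#' @export
summary.rlmpi_fit <- function(object, ...) {
  W <- object$proportions$values
  est <- !object$inestimable
  s <- list(n_samples = ncol(W),
            n_cell_types = nrow(W),
            n_features = length(object$features_used),
            pct_inestimable = 100 * mean(object$inestimable),
            mean_proportions = if (any(est)) rowMeans(W[, est, drop = FALSE]) else
              setNames(rep(NA_real_, nrow(W)), rownames(W)),
            condition_number = object$reference$condition_number)
  class(s) <- "summary.rlmpi_fit"
  s
}

#' @export
print.summary.rlmpi_fit <- function(x, ...) {
  cat("RLM-PI deconvolution summary\n")
  cat(sprintf("  samples: %d   cell types: %d   signature features: %d\n",
              x$n_samples, x$n_cell_types, x$n_features))
  cat(sprintf("  inestimable: %.1f%%   reference condition number: %.3g\n",
              x$pct_inestimable, x$condition_number))
  cat("  mean proportions over estimable samples:\n")
  print(round(x$mean_proportions, 4))
  invisible(x)
}

#' @export
coef.rlmpi_fit <- function(object, raw = FALSE, ...) {
  if (raw) object$raw_coefficients else object$proportions$values
}

#' @export
fitted.rlmpi_fit <- function(object, ...) {
  W <- object$proportions$values
  W[is.na(W)] <- 0
  object$reference$values %*% W
}

#' @export
residuals.rlmpi_fit <- function(object, ...) {
  object$bulk - fitted(object)
}

#' @export
plot.rlmpi_fit <- function(x, ...) {
  W <- x$proportions$values
  W0 <- W; W0[is.na(W0)] <- 0
  graphics::barplot(W0, col = grDevices::hcl.colors(nrow(W), "viridis"),
                    border = NA, las = 2, ylab = "proportion",
                    main = "Estimated cell-type proportions", ...)
  graphics::legend("topright", legend = rownames(W), bty = "n",
                   fill = grDevices::hcl.colors(nrow(W), "viridis"))
  invisible(x)
}

#' Two-stage hierarchical deconvolution
#'
#' Stage 1 estimates proportions of the general cell types (e.g. epithelial,
#' adipose, fibroblast, immune) from `A_general`; stage 2 estimates the
#' epithelial subtype composition from `A_subtypes`, summing to 1 within the
#' epithelium. Tissue-relative subtype proportions are the stage-2 fractions
#' scaled by the stage-1 epithelial proportion, so their column sums equal
#' the epithelial proportion exactly.
#'
#' @param A_general [reference_matrix()] for the general cell types; must
#'   contain the column `epithelial_label`.
#' @param A_subtypes [reference_matrix()] for the epithelial subtypes.
#' @param X a [feature_matrix()] of bulk samples.
#' @param epithelial_label the general cell type whose compartment the
#'   subtypes partition (default `"epithelial"`).
#' @param ... passed to [deconvolve()].
#' @return an object of class `hierarchical_fit` with mixing matrices
#'   `general`, `subtypes_within_epithelium` and `subtypes_tissue_relative`,
#'   plus both stage fits.
#' @export
hierarchical_deconvolve <- function(A_general, A_subtypes, X,
                                    epithelial_label = "epithelial", ...) {
  stopifnot(inherits(A_general, "reference_matrix"),
            inherits(A_subtypes, "reference_matrix"))
  if (!epithelial_label %in% colnames(A_general$values)) {
    stop("epithelial label '", epithelial_label, "' is not a column of A_general",
         call. = FALSE)
  }
  stage1 <- deconvolve(A_general, X, ...)
  stage2 <- deconvolve(A_subtypes, X, ...)
  epi <- stage1$proportions$values[epithelial_label, ]
  Wsub <- stage2$proportions$values
  Wrel <- sweep(Wsub, 2, epi, `*`)
  flags <- stage2$proportions$inestimable |
    matrix(rep(stage1$inestimable, each = nrow(Wsub)), nrow(Wsub), ncol(Wsub))
  Wrel[flags] <- NA_real_
  rel <- structure(list(values = Wrel, inestimable = flags), class = "mixing_matrix")
  structure(list(general = stage1$proportions,
                 subtypes_within_epithelium = stage2$proportions,
                 subtypes_tissue_relative = rel,
                 stage1 = stage1, stage2 = stage2,
                 epithelial_label = epithelial_label),
            class = "hierarchical_fit")
}

#' @export
print.hierarchical_fit <- function(x, ...) {
  cat("Hierarchical RLM-PI deconvolution\n")
  cat(sprintf("  stage 1 (general types): %s\n",
              paste(rownames(x$general$values), collapse = ", ")))
  cat(sprintf("  stage 2 (subtypes within '%s'): %s\n", x$epithelial_label,
              paste(rownames(x$subtypes_within_epithelium$values), collapse = ", ")))
  invisible(x)
}
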
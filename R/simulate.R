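# Robustness simulation and synthetic-data generators.
#
# The robustness experiment follows the design used to validate the RLM-PI
# estimator: draw mixing weights uniformly, form noiseless bulk mixtures
# X = A W, replace a chosen fraction of entries with U(0,1) noise, deconvolve,
# and summarise parameter-recovery MSE and the percentage of inestimable
# proportions across repetitions.

#' Simulate bulk mixtures from a signature matrix
#'
#' Mixing weights are drawn i.i.d. U(0,1) and, by default, each column is
#' normalised to sum to 1 so the weights are proportions; `raw_uniform = TRUE`
#' skips the normalisation (the literal unnormalised design). The bulk matrix
#' is the noiseless product `X = A W`; for beta-valued references the convex
#' combination keeps every entry in \[0,1\] (clipped defensively otherwise).
#'
#' @param A a [reference_matrix()].
#' @param n number of bulk samples (default 100).
#' @param seed RNG seed.
#' @param raw_uniform keep the raw U(0,1) weights unnormalised.
#' @return list with `W_true` (a [mixing_matrix()], or a plain matrix when
#'   `raw_uniform`) and `X` (a [feature_matrix()]).
#' @export
simulate_mixtures <- function(A, n = 100, seed = 1, raw_uniform = FALSE) {
  stopifnot(inherits(A, "reference_matrix"), n >= 1)
  set.seed(seed)
  k <- ncol(A$values)
  W <- matrix(stats::runif(k * n), k, n,
              dimnames = list(colnames(A$values), paste0("sim", seq_len(n))))
  if (!raw_uniform) W <- sweep(W, 2, colSums(W), `/`)
  X <- A$values %*% W
  if (A$modality == "dname_beta") X <- pmin(pmax(X, 0), 1)
  list(W_true = if (raw_uniform) W else mixing_matrix(W),
       X = feature_matrix(X, A$modality))
}

#' Corrupt a fraction of matrix entries with uniform noise
#'
#' Exactly `round(fraction * p * n)` entries, chosen uniformly without
#' replacement over all (feature, sample) positions, are replaced by i.i.d.
#' U(0,1) draws; every other entry is untouched.
#'
#' @param X a [feature_matrix()].
#' @param fraction fraction of entries to replace, in \[0,1\].
#' @param seed RNG seed.
#' @return a corrupted [feature_matrix()].
#' @export
corrupt_with_noise <- function(X, fraction, seed = 1) {
  stopifnot(inherits(X, "feature_matrix"), fraction >= 0, fraction <= 1)
  v <- X$values
  n_corrupt <- round(fraction * length(v))
  if (n_corrupt > 0) {
    set.seed(seed)
    idx <- sample.int(length(v), n_corrupt)
    v[idx] <- stats::runif(n_corrupt)
  }
  feature_matrix(v, X$modality)
}

#' Noise-corruption robustness experiment
#'
#' For each repetition and noise level: simulate `n` mixtures from `A`,
#' corrupt the stated fraction of entries, deconvolve, and record the mean
#' squared error between estimated and true proportions over the estimable
#' columns together with the percentage of inestimable proportions.
#' Aggregates per noise level are the mean across repetitions with a
#' percentile-bootstrap 95% CI.
#'
#' @param A a [reference_matrix()].
#' @param n bulk samples per repetition (default 100).
#' @param b repetitions (default 1000; reduce for desk-scale runs).
#' @param noise_grid noise fractions (default `seq(0, 0.8, by = 0.2)`).
#' @param seed master seed; all randomness derives from it.
#' @param n_boot bootstrap resamples for the CI (default 1000).
#' @return an object of class `robustness_report`: a data frame with columns
#'   `noise`, `mean_mse`, `ci_lower`, `ci_upper`, `pct_inestimable`, carrying
#'   the configuration and per-rep MSE draws as attributes.
#' @export
robustness_experiment <- function(A, n = 100, b = 1000,
                                  noise_grid = seq(0, 0.8, by = 0.2),
                                  seed = 1, n_boot = 1000) {
  stopifnot(inherits(A, "reference_matrix"), b >= 1,
            all(noise_grid >= 0 & noise_grid <= 1))
  set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1, b * (length(noise_grid) + 1)),
                      nrow = b)
  mse <- matrix(NA_real_, b, length(noise_grid))
  inest <- matrix(0, b, length(noise_grid))
  for (r in seq_len(b)) {
    sim <- simulate_mixtures(A, n = n, seed = sub_seeds[r, 1])
    Wt <- sim$W_true$values
    for (g in seq_along(noise_grid)) {
      Xc <- corrupt_with_noise(sim$X, noise_grid[g], seed = sub_seeds[r, g + 1])
      fit <- deconvolve(A, Xc)
      est <- !fit$inestimable
      if (any(est)) {
        mse[r, g] <- mean((fit$proportions$values[, est, drop = FALSE] -
                             Wt[, est, drop = FALSE])^2)
      }
      inest[r, g] <- 100 * mean(fit$proportions$inestimable)
    }
  }
  boot_ci <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_))
    if (length(x) == 1) return(c(x, x))
    bm <- vapply(seq_len(n_boot), function(i) mean(sample(x, replace = TRUE)),
                 numeric(1))
    stats::quantile(bm, c(0.025, 0.975), names = FALSE)
  }
  set.seed(seed + 1)
  cis <- apply(mse, 2, boot_ci)
  rep_df <- data.frame(noise = noise_grid,
                       mean_mse = colMeans(mse, na.rm = TRUE),
                       ci_lower = cis[1, ],
                       ci_upper = cis[2, ],
                       pct_inestimable = colMeans(inest))
  attr(rep_df, "config") <- list(n = n, b = b, noise_grid = noise_grid,
                                 seed = seed, k = ncol(A$values),
                                 p = nrow(A$values))
  attr(rep_df, "mse_reps") <- mse
  class(rep_df) <- c("robustness_report", "data.frame")
  rep_df
}

#' @export
print.robustness_report <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Robustness report: %d reps of %d samples, %dx%d reference\n",
              cfg$b, cfg$n, cfg$p, cfg$k))
  print.data.frame(round(as.data.frame(x), 6))
  invisible(x)
}

#' @export
plot.robustness_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$noise, x$mean_mse, type = "b", xlab = "noise fraction",
                 ylab = "mean MSE", main = "Parameter recovery", ...)
  graphics::lines(x$noise, x$ci_lower, lty = 2)
  graphics::lines(x$noise, x$ci_upper, lty = 2)
  graphics::plot(x$noise, x$pct_inestimable, type = "b", xlab = "noise fraction",
                 ylab = "% inestimable", main = "Inestimable proportions", ...)
  invisible(x)
}

#' Write a robustness report to TSV
#'
#' @param report a `robustness_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_robustness_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Generate a block-structured beta-valued signature matrix
#'
#' Each cell type receives `floor(p/k)` signature loci whose beta value sits
#' `separation` above a common baseline, with small uniform jitter
#' everywhere; leftover loci stay at baseline. The default shape (58 loci,
#' 3 types) mirrors a realistic methylation signature for three epithelial
#' subtypes.
#'
#' @param p number of loci (default 58).
#' @param k number of cell types (default 3).
#' @param separation beta difference between signature and baseline loci
#'   (default 0.5); `0` produces a deliberately degenerate rank-1 matrix
#'   (with a warning).
#' @param baseline baseline beta level (default 0.15).
#' @param jitter half-width of the uniform jitter (default 0.02).
#' @param seed RNG seed.
#' @return a [reference_matrix()] (`dname_beta`).
#' @export
make_synthetic_reference <- function(p = 58, k = 3, separation = 0.5,
                                     baseline = 0.15, jitter = 0.02, seed = 1) {
  stopifnot(p >= k, k >= 1, separation >= 0, separation <= 1)
  set.seed(seed)
  A <- matrix(baseline, p, k,
              dimnames = list(sprintf("locus%03d", seq_len(p)),
                              paste0("type", seq_len(k))))
  block <- p %/% k
  for (l in seq_len(k)) {
    rows <- ((l - 1) * block + 1):(l * block)
    A[rows, l] <- baseline + separation
  }
  A <- A + matrix(stats::runif(p * k, -jitter, jitter), p, k)
  if (min(A) < 0 || max(A) > 1) {
    warning("values clipped into [0,1]", call. = FALSE)
    A <- pmin(pmax(A, 0), 1)
  }
  if (separation == 0) {
    warning("separation 0: no cell-type signal, the reference is effectively rank-deficient",
            call. = FALSE)
  }
  reference_matrix(A, "dname_beta", check_rank = separation > 0)
}

#' Generate labelled synthetic single-cell counts with planted structure
#'
#' Negative-binomial counts with per-type marker blocks upregulated by
#' `effect`, log-normal library-size factors and balanced true labels. A
#' quarter of the genes are markers, split evenly across types; the planted
#' marker assignment is attached as attribute `"marker_genes"`.
#'
#' @param m number of cells (default 300; must be at least `3 * k`).
#' @param p number of genes (default 200).
#' @param k number of cell types (default 3).
#' @param effect marker fold-change (default 8; `1` gives pure null data).
#' @param base_mean median baseline expression per gene (default 2).
#' @param dispersion NB dispersion (default 0.3).
#' @param lib_sd standard deviation of log library-size factors (default 0.3).
#' @param seed RNG seed.
#' @return a labelled [cell_matrix()].
#' @export
make_synthetic_sc <- function(m = 300, p = 200, k = 3, effect = 8,
                              base_mean = 2, dispersion = 0.3, lib_sd = 0.3,
                              seed = 1) {
  stopifnot(m >= 3 * k, p >= 2 * k, effect >= 0)
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(p))
  types <- paste0("type", seq_len(k))
  labels <- rep(types, length.out = m)
  mu0 <- stats::rlnorm(p, log(base_mean), 0.5)
  sj <- stats::rlnorm(m, 0, lib_sd)
  n_marker <- max(1L, (p %/% 4L) %/% k)
  marker_of <- rep(NA_character_, p)
  for (l in seq_len(k)) {
    marker_of[((l - 1) * n_marker + 1):(l * n_marker)] <- types[l]
  }
  mu <- outer(mu0, sj)
  for (l in seq_len(k)) {
    rows <- which(marker_of == types[l])
    cols <- which(labels == types[l])
    mu[rows, cols] <- mu[rows, cols] * effect
  }
  counts <- matrix(stats::rnbinom(p * m, mu = mu, size = 1 / dispersion), p, m,
                   dimnames = list(genes, paste0("cell", seq_len(m))))
  Y <- cell_matrix(counts, labels = labels)
  attr(Y, "marker_genes") <- split(genes[!is.na(marker_of)],
                                   marker_of[!is.na(marker_of)])
  Y
}
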
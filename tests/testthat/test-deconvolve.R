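test_that("robust fit solves exact systems and matches OLS without outliers", {
  A <- reference_matrix(diag(2) * 0.99 + 0.005, "dname_beta",
                        feature_ids = c("f1", "f2"),
                        cell_type_names = c("a", "b"))
  f <- rlm_fit(A, c(f1 = 0.3, f2 = 0.7))
  expect_equal(unname(f$coefficients), unname(solve(A$values, c(0.3, 0.7))),
               tolerance = 1e-8)

  A3 <- make_synthetic_reference(p = 30, k = 3, seed = 61)
  w <- c(0.2, 0.5, 0.3)
  x <- drop(A3$values %*% w)
  names(x) <- rownames(A3$values)
  f3 <- rlm_fit(A3, x)
  expect_true(f3$converged)
  expect_equal(unname(f3$coefficients), w, tolerance = 1e-6)
  ols <- qr.solve(A3$values, x)
  expect_equal(unname(f3$coefficients), unname(ols), tolerance = 1e-6)
})

test_that("robust fit beats OLS under sparse uniform corruption", {
  A <- make_synthetic_reference(p = 58, k = 3, seed = 62)
  w <- c(0.25, 0.45, 0.30)
  wins <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- drop(A$values %*% w)
    idx <- sample(58, 6)  # 10% of entries replaced by noise
    x[idx] <- runif(6)
    names(x) <- rownames(A$values)
    rob <- rlm_fit(A, x)$coefficients
    ols <- qr.solve(A$values, x)
    if (sum((rob - w)^2) < sum((ols - w)^2)) wins <- wins + 1
  }
  expect_gte(wins, 80)
})

test_that("adaptive noise threshold zeroes by the most-negative magnitude", {
  expect_equal(adaptive_noise_threshold(c(0.6, 0.5, -0.1)), c(0.6, 0.5, 0))
  expect_equal(adaptive_noise_threshold(c(0.05, 0.6, -0.1, 0.45)),
               c(0, 0.6, 0, 0.45))
  expect_equal(adaptive_noise_threshold(c(0.3, 0.7)), c(0.3, 0.7))
  expect_equal(adaptive_noise_threshold(c(-0.2, 0.1)), c(0, 0))
  # alternative reading: only negatives zeroed
  expect_equal(adaptive_noise_threshold(c(0.05, 0.6, -0.1, 0.45),
                                        most_negative_only = TRUE),
               c(0.05, 0.6, 0, 0.45))
  # never produces negatives, for random vectors
  set.seed(63)
  for (i in 1:50) {
    out <- adaptive_noise_threshold(rnorm(5))
    expect_gte(min(out), 0)
  }
})

test_that("proportion normalisation sums to one and flags the zero vector", {
  expect_equal(normalize_proportions(c(0.6, 0.5, 0)), c(6 / 11, 5 / 11, 0))
  expect_equal(normalize_proportions(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  z <- normalize_proportions(c(0, 0, 0))
  expect_true(attr(z, "inestimable"))
  expect_error(normalize_proportions(c(-0.1, 0.5)), "non-negative")
  # idempotent
  p <- normalize_proportions(c(2, 3, 5))
  expect_equal(normalize_proportions(p), p, tolerance = 1e-15)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("deconvolution recovers noiseless mixtures and stays column-stochastic", {
  A <- make_synthetic_reference(p = 58, k = 3, seed = 64)
  W_true <- random_props(3, 50, seed = 65)
  X <- feature_matrix(A$values %*% W_true, "dname_beta")
  fit <- deconvolve(A, X)
  expect_s3_class(fit, "rlmpi_fit")
  expect_identical(dim(coef(fit)), c(3L, 50L))
  expect_lt(mean((coef(fit) - W_true)^2), 1e-6)
  expect_lt(max(abs(coef(fit) - W_true)), 1e-4)
  expect_equal(sum(fit$inestimable), 0)
  expect_true(all(coef(fit) >= 0))
  expect_equal(colSums(coef(fit)), rep(1, 50), tolerance = 1e-8,
               ignore_attr = TRUE)
  # model-object methods behave
  expect_equal(dim(residuals(fit)), dim(fitted(fit)))
  expect_lt(max(abs(residuals(fit))), 1e-8)
  s <- summary(fit)
  expect_equal(s$pct_inestimable, 0)
  expect_output(print(fit), "RLM-pseudo-inverse")
})

test_that("proportions are invariant to positive scaling of an RNA sample", {
  set.seed(66)
  Av <- matrix(rexp(40 * 3, rate = 0.1), 40, 3)
  A <- reference_matrix(Av, "rna_counts")
  w <- c(0.3, 0.3, 0.4)
  x <- drop(Av %*% w) + abs(rnorm(40, sd = 2))
  X1 <- feature_matrix(matrix(x, dimnames = list(rownames(Av), "s")), "rna_counts")
  X2 <- feature_matrix(matrix(7.3 * x, dimnames = list(rownames(Av), "s")), "rna_counts")
  f1 <- deconvolve(A, X1)
  f2 <- deconvolve(A, X2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("modality and overlap mismatches are rejected", {
  A <- make_synthetic_reference(p = 20, k = 2, seed = 67)
  X_rna <- feature_matrix(matrix(1:20, 10, 2,
                                 dimnames = list(paste0("g", 1:10), c("s1", "s2"))),
                          "rna_counts")
  expect_error(deconvolve(A, X_rna), "modality")
  X_far <- feature_matrix(matrix(runif(20), 10, 2,
                                 dimnames = list(paste0("zz", 1:10), c("s1", "s2"))),
                          "dname_beta")
  expect_error(deconvolve(A, X_far), "overlap")
})

test_that("hierarchical estimation composes the two stages multiplicatively", {
  set.seed(68)
  # subtype loci are chosen so non-epithelial lineages sit at a flat low-beta
  # baseline (the locus-selection criteria demand low non-epithelial variance
  # and a large delta-beta), so the non-epithelial profiles here are near the
  # generator's baseline
  sub <- make_synthetic_reference(p = 40, k = 3, seed = 69)
  colnames(sub$values) <- c("lp", "lm", "basal")
  A_sub <- reference_matrix(sub$values, "dname_beta")
  gen_v <- cbind(epithelial = rowMeans(sub$values),
                 adipose = runif(40, 0.08, 0.22),
                 immune = runif(40, 0.10, 0.30))
  rownames(gen_v) <- rownames(sub$values)
  A_gen <- reference_matrix(gen_v, "dname_beta")

  # planted truth: epithelial fraction 0.6, subtype split (0.5, 0.3, 0.2)
  sub_frac <- c(0.5, 0.3, 0.2)
  epi_prof <- drop(sub$values %*% sub_frac)
  bulk <- 0.6 * epi_prof + 0.4 * gen_v[, "adipose"]
  X <- feature_matrix(matrix(bulk, dimnames = list(rownames(gen_v), "s1")),
                      "dname_beta")
  h <- hierarchical_deconvolve(A_gen, A_sub, X, epithelial_label = "epithelial")
  epi_hat <- h$general$values["epithelial", 1]
  expect_lt(abs(epi_hat - 0.6), 0.05)
  expect_lt(max(abs(h$subtypes_within_epithelium$values[, 1] - sub_frac)), 0.05)
  # column sums of tissue-relative proportions equal the epithelial proportion
  expect_equal(sum(h$subtypes_tissue_relative$values[, 1]), epi_hat,
               tolerance = 1e-8)
  # multiplication contract
  expect_equal(h$subtypes_tissue_relative$values[, 1],
               h$subtypes_within_epithelium$values[, 1] * epi_hat,
               tolerance = 1e-12)
  expect_error(hierarchical_deconvolve(A_gen, A_sub, X, epithelial_label = "nope"),
               "not a column")
})

test_that("zero epithelial fraction gives zero tissue-relative subtypes", {
  sub <- make_synthetic_reference(p = 40, k = 3, seed = 70)
  A_sub <- reference_matrix(sub$values, "dname_beta")
  gen_v <- cbind(epithelial = rowMeans(sub$values),
                 adipose = rep(0.85, 40), immune = rep(0.05, 40))
  rownames(gen_v) <- rownames(sub$values)
  gen_v["locus001", "immune"] <- 0.06  # keep columns distinct from constants
  A_gen <- reference_matrix(gen_v, "dname_beta")
  bulk <- gen_v[, "adipose"]
  X <- feature_matrix(matrix(bulk, dimnames = list(rownames(gen_v), "s1")),
                      "dname_beta")
  h <- hierarchical_deconvolve(A_gen, A_sub, X)
  expect_equal(h$general$values["epithelial", 1], 0, tolerance = 1e-6)
  expect_equal(unname(h$subtypes_tissue_relative$values[, 1]), rep(0, 3),
               tolerance = 1e-6)
})
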
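test_that("pre-selection statistic matches hand-built and exhaustive cases", {
  # feature engineered to mean_in 0.9, mean_out 0.1, var_out 0.01 -> stat 8
  e <- sqrt(0.005)
  v <- rbind(sig = c(0.8, 1.0, 0.1 - e, 0.1 + e),
             sig2 = c(0.7, 0.9, 0.2 - e, 0.2 + e),
             null = c(0.5, 0.5, 0.5, 0.5),
             neg = c(0.1, 0.1, 0.5 - e, 0.5 + e))
  colnames(v) <- paste0("c", 1:4)
  Y <- toy_cells(v, c("in", "in", "out", "out"))
  keep <- preselect_features(Y, "in", lambda = 2)
  stat <- attr(keep, "statistic")
  expect_equal(unname(stat["sig"]), 8, tolerance = 1e-10)
  expect_equal(unname(stat["null"]), 0)
  expect_setequal(as.character(keep), c("sig", "sig2"))

  # 50-feature random matrix: passing set equals brute-force evaluation
  set.seed(21)
  m <- matrix(rexp(50 * 12), 50, 12,
              dimnames = list(sprintf("f%02d", 1:50), paste0("c", 1:12)))
  lab <- rep(c("t1", "t2", "t3"), each = 4)
  Yr <- toy_cells(m, lab)
  got <- preselect_features(Yr, "t2", lambda = 0.5)
  manual <- character(0)
  for (f in rownames(m)) {
    s <- (mean(m[f, lab == "t2"]) - mean(m[f, lab != "t2"])) /
      sqrt(var(m[f, lab != "t2"]))
    if (s > 0.5) manual <- c(manual, f)
  }
  expect_setequal(as.character(got), manual)

  expect_error(preselect_features(Yr, "t2", lambda = 1e9), "lower lambda")
})

test_that("Mahalanobis scores reduce to signed squared differences under identity", {
  d <- mahalanobis_scores(c(f1 = 2, f2 = -1, f3 = 0.5), diag(3), epsilon_scale = 0)
  expect_equal(as.vector(d), c(4, -1, 0.25))
  expect_equal(order(-d), c(1, 3, 2))  # rank f1, f3, f2
})

test_that("Mahalanobis ranking matches a dense-inverse oracle and discounts duplicates", {
  # 4 features; f2 is a correlated duplicate of top feature f1
  set.seed(31)
  n_out <- 40
  base <- rnorm(n_out)
  out_cells <- rbind(f1 = 1 + base * 0.5,
                     f2 = 1 + base * 0.5 + rnorm(n_out, sd = 0.05),
                     f3 = 1 + rnorm(n_out, sd = 0.5),
                     f4 = 1 + rnorm(n_out, sd = 0.5))
  in_cells <- matrix(c(3, 3, 2.2, 1.0), 4, 6) + rnorm(24, sd = 0.05)
  rownames(in_cells) <- rownames(out_cells)
  v <- cbind(in_cells, out_cells)
  v <- v - min(v)  # keep counts-style non-negativity
  colnames(v) <- paste0("c", seq_len(ncol(v)))
  Y <- toy_cells(v, rep(c("in", "out"), c(6, n_out)))
  rk <- rank_features_mahalanobis(Y, "in")

  # dense explicit-inverse oracle on the same regularised covariance
  outv <- v[, 7:ncol(v)]
  delta <- rowMeans(v[, 1:6]) - rowMeans(outv)
  S <- cov(t(outv))
  Sreg <- S + diag(1e-6 * mean(diag(S)), 4)
  d_oracle <- drop(solve(Sreg) %*% (delta * abs(delta)))
  names(d_oracle) <- rownames(v)
  expect_equal(rk$scores[names(d_oracle)[order(-d_oracle)]],
               d_oracle[order(-d_oracle)], tolerance = 1e-10)
  # the duplicated pair shares its signal: both rank below uncorrelated f3
  expect_lt(which(rk$features == "f3"),
            max(which(rk$features %in% c("f1", "f2"))))

  # all-zero differences: zero scores, ties broken by feature ID
  set.seed(33)
  block <- matrix(runif(16, 1, 5), 4, 4,
                  dimnames = list(c("fb", "fa", "fd", "fc"), NULL))
  vz <- cbind(block, block)  # identical cells in both groups -> delta = 0
  colnames(vz) <- paste0("c", 1:8)
  Yz <- toy_cells(vz, rep(c("in", "out"), each = 4))
  rz <- rank_features_mahalanobis(Yz, "in")
  expect_equal(unname(rz$scores), rep(0, 4))
  expect_equal(rz$features, c("fa", "fb", "fc", "fd"))
})

test_that("ranking with exactly diagonal covariance reproduces per-feature ordering", {
  means <- c(1, 2, 3, 4)
  sds <- c(0.2, 0.1, 0.3, 0.15)
  out_cells <- diagonal_cov_outgroup(means, sds, n_cells = 12, seed = 5)
  rownames(out_cells) <- paste0("f", 1:4)
  in_shift <- c(0.5, -0.2, 0.9, 0.05)
  in_cells <- matrix(means + in_shift, 4, 5)
  rownames(in_cells) <- rownames(out_cells)
  v <- cbind(in_cells, out_cells)
  v <- v - min(v)
  colnames(v) <- paste0("c", seq_len(ncol(v)))
  Y <- toy_cells(v, rep(c("in", "out"), c(5, 12)))
  rk <- rank_features_mahalanobis(Y, "in", epsilon_scale = 0)
  # sample covariance is exactly diagonal, so d_i = delta_i|delta_i| / var_i
  d_manual <- in_shift * abs(in_shift) / sds^2
  names(d_manual) <- paste0("f", 1:4)
  expect_equal(rk$features, names(sort(-d_manual)))
  expect_equal(rk$scores, d_manual[rk$features], tolerance = 1e-8)
})

test_that("NB DE ranking separates planted genes and respects label symmetry", {
  set.seed(41)
  m <- matrix(rnbinom(60 * 40, mu = 5, size = 2), 60, 40,
              dimnames = list(sprintf("g%02d", 1:60), paste0("c", 1:40)))
  m["g01", 1:20] <- rnbinom(20, mu = 60, size = 2)   # strongly up in group a
  m["g01", 21:40] <- 0                               # silent in group b
  Y <- toy_cells(m, rep(c("a", "b"), each = 20))
  rk <- rank_features_de(Y, "a")
  expect_equal(rk$features[1], "g01")
  expect_lt(unname(rk$p_values[1]), 1e-6)

  # swapping group labels flips every z statistic, reversing the ranking
  rk_b <- rank_features_de(Y, "b")
  expect_equal(sort(rk$scores[rk$features]),
               sort(-rk_b$scores[rk$features]), tolerance = 1e-10)
  expect_equal(rk_b$features[length(rk_b$features)], "g01")

  expect_error(rank_features_de(cell_matrix(m), "a"), "labels")
})

test_that("DE p-values are calibrated under the null", {
  Y0 <- make_synthetic_sc(m = 200, p = 400, k = 2, effect = 1, seed = 13)
  rk <- rank_features_de(Y0, "type1")
  ks <- suppressWarnings(stats::ks.test(rk$p_values, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("signature assembly takes the top-n union and group means", {
  Y <- make_synthetic_sc(m = 30, p = 40, k = 3, effect = 6, seed = 17)
  types <- sort(unique(Y$labels))
  rankings <- lapply(types, function(tp) {
    rank_features_mahalanobis(Y, tp, preselect_features(Y, tp, top_n = 40))
  })
  names(rankings) <- types

  # disjoint top lists give p' = k * top_n rows
  disjoint <- rankings
  disjoint[[1]]$features <- sprintf("gene%04d", 1:10)
  disjoint[[2]]$features <- sprintf("gene%04d", 11:20)
  disjoint[[3]]$features <- sprintf("gene%04d", 21:30)
  A_dis <- build_reference(Y, disjoint, top_n = 10)
  expect_equal(nrow(A_dis$values), 30)

  # shared top features collapse in the union; a union below k is an error
  shared <- rankings
  shared[[1]]$features <- c("gene0001", "gene0002")
  shared[[2]]$features <- c("gene0001", "gene0002")
  shared[[3]]$features <- c("gene0003", "gene0004")
  expect_equal(nrow(build_reference(Y, shared, top_n = 2)$values), 4)
  too_few <- rankings
  too_few[[1]]$features <- "gene0001"
  too_few[[2]]$features <- "gene0001"
  too_few[[3]]$features <- "gene0002"
  expect_error(build_reference(Y, too_few, top_n = 1), "smaller than")

  # column means match a direct oracle, and cell order does not matter
  A <- build_reference(Y, rankings, top_n = 5)
  for (tp in types) {
    expect_equal(A$values[, tp],
                 rowMeans(Y$values[rownames(A$values), Y$labels == tp]),
                 tolerance = 1e-12)
  }
  perm <- sample(ncol(Y$values))
  Yp <- cell_matrix(Y$values[, perm], labels = Y$labels[perm])
  rankings_p <- lapply(types, function(tp) {
    rank_features_mahalanobis(Yp, tp, preselect_features(Yp, tp, top_n = 40))
  })
  names(rankings_p) <- types
  Ap <- build_reference(Yp, rankings_p, top_n = 5)
  expect_equal(Ap$values, A$values, tolerance = 1e-10)
})

test_that("DNAme locus selection enforces all three criteria", {
  # single hand-checked locus: var(non-epi) = 1e-4 < 1e-3, |0.80 - 0.11| >= 0.5
  nonepi <- beta_fm(matrix(c(0.10, 0.12, 0.11), 1, 3,
                           dimnames = list("cgA", c("fib", "imm", "adi"))))
  epi <- beta_fm(matrix(0.80, 1, 1, dimnames = list("cgA", "lp")))
  A <- select_dname_loci(epi, nonepi, quota = 5)
  expect_true("cgA" %in% rownames(A$values))

  # high non-epithelial variance fails criterion (1)
  nonepi_bad <- beta_fm(matrix(c(0.1, 0.5, 0.9), 1, 3,
                               dimnames = list("cgA", c("fib", "imm", "adi"))))
  expect_error(select_dname_loci(epi, nonepi_bad, quota = 5), "no candidate")

  # planted toy: 5 true loci per subtype among decoys violating one criterion each
  set.seed(51)
  subtypes <- c("lp", "lm", "basal")
  loci <- list()
  truth <- list()
  mk_locus <- function(id, epi_row, nonepi_row) {
    loci[[id]] <<- list(epi = epi_row, nonepi = nonepi_row)
  }
  n_id <- 0
  for (s in seq_along(subtypes)) {
    for (r in 1:5) {
      n_id <- n_id + 1
      id <- sprintf("true_%s_%02d", subtypes[s], r)
      epi_row <- c(0.05, 0.05, 0.05); epi_row[s] <- 0.95
      mk_locus(id, epi_row, c(0.10, 0.11, 0.12))
      truth[[subtypes[s]]] <- c(truth[[subtypes[s]]], id)
    }
  }
  for (r in 1:100) {
    id <- sprintf("decoy_%03d", r)
    if (r %% 2 == 0) {
      mk_locus(id, c(0.9, 0.9, 0.9), runif(3))          # fails (1): variable non-epi
    } else {
      mk_locus(id, c(0.3, 0.3, 0.3), c(0.10, 0.11, 0.12))  # fails (2): |delta| < 0.5
    }
  }
  epi_m <- t(vapply(loci, `[[`, numeric(3), "epi"))
  nonepi_m <- t(vapply(loci, `[[`, numeric(3), "nonepi"))
  colnames(epi_m) <- subtypes; colnames(nonepi_m) <- c("fib", "imm", "adi")
  A2 <- select_dname_loci(beta_fm(epi_m), beta_fm(nonepi_m), quota = 5)
  expect_setequal(rownames(A2$values), unlist(truth))
  picks <- attr(A2, "selected_by_subtype")
  for (s in subtypes) expect_setequal(picks[[s]], truth[[s]])

  # re-check criteria (1)-(2) independently on the output
  for (id in rownames(A2$values)) {
    expect_lt(var(nonepi_m[id, ]), 0.001)
    expect_true(any(abs(A2$values[id, ] - mean(nonepi_m[id, ])) >= 0.5))
  }
})
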
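test_that("autoscaling centers and scales as specified", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  sc <- autoscale(X)
  expect_equal(unname(sc$values[, "a"]), c(-1, 0, 1))
  expect_equal(unname(sc$values[, "b"]), c(0, 0, 0))   # constant: centered, scale 1
  expect_true(sc$constant_columns[["b"]])
  expect_equal(autoscale(X, mode = "none")$values, X)
  expect_error(autoscale(X[1, , drop = FALSE]), "2 rows")
  # unit-variance invariant on non-constant columns
  set.seed(1); Y <- matrix(rnorm(200), 20)
  sy <- autoscale(Y)
  expect_lt(max(abs(colMeans(sy$values))), 1e-10)
  expect_equal(apply(sy$values, 2, sd), rep(1, 10), tolerance = 1e-10)
})

test_that("PCA is an exact SVD decomposition with correct variance accounting", {
  set.seed(2)
  u <- rnorm(10); v <- rnorm(4)
  X1 <- u %*% t(v)                                    # rank 1 (centered below)
  p1 <- fit_pca(X1, 1)
  expect_gt(p1$explained_variance_fraction[1], 1 - 1e-10)

  X <- matrix(rnorm(60), 10, 6)
  k <- min(nrow(X) - 1, ncol(X))
  pf <- fit_pca(X, k)
  expect_equal(sum(pf$explained_variance_fraction), 1, tolerance = 1e-10)
  expect_true(all(diff(pf$explained_variance_fraction) <= 1e-12))
  # orthonormal loadings, exact reconstruction at full rank
  expect_equal(crossprod(pf$loadings), diag(k), tolerance = 1e-8)
  recon <- pf$scores %*% t(pf$loadings)
  expect_equal(recon, sweep(X, 2, colMeans(X)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(fit_pca(X, 10), "exceeds")
})

test_that("element-wise cross-validated Q2 separates structure from noise", {
  set.seed(3)
  u <- rnorm(30); v <- rnorm(8)
  X <- u %*% t(v) + matrix(rnorm(240, sd = 0.01), 30)   # near rank 1
  q <- pca_q2(X, 1, seed = 1)
  expect_gt(q[1], 0.95)
  N <- matrix(rnorm(240), 30, 8)                        # pure noise
  qn <- pca_q2(N, 1, seed = 1)
  expect_lte(qn[1], 0.1)
  expect_identical(pca_q2(X, 2, seed = 5), pca_q2(X, 2, seed = 5))
  expect_error(pca_q2(X[1:3, ], 1, n_folds = 7), "n_folds")
})

test_that("HCA recovers constructed clusters and is row-order invariant", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 8), 10))
  res <- hca(X, k = 2)
  expect_equal(pair_count_ari(res$labels, rep(1:2, each = 10)), 1)
  expect_equal(unname(hca(X[1, , drop = FALSE], k = 1)$labels), 1)
  expect_error(hca(X, k = 21), "exceeds")
  perm <- sample(nrow(X))
  res_p <- hca(X[perm, ], k = 2)
  expect_equal(pair_count_ari(res_p$labels, res$labels[perm]), 1)
})

test_that("HCA on the default synthetic profile recovers the four groups", {
  tab <- generate_compound_table(synthetic_config(seed = 1))
  res <- hca(autoscale(tab$concentrations), linkage = "ward",
             metric = "euclidean", k = 4)
  expect_gte(pair_count_ari(res$labels, attr(tab, "group")), 0.9)
})

test_that("first two PCs dominate when between-group variance dominates", {
  tab <- generate_compound_table(synthetic_config(seed = 2, compound_cv = 0.05))
  p <- fit_pca(autoscale(tab$concentrations), 2)
  expect_gt(sum(p$explained_variance_fraction), 0.6)
})

test_that("OPLS-DA satisfies its algebraic identities", {
  tab <- generate_compound_table(synthetic_config(seed = 6))
  g <- attr(tab, "group"); sel <- g %in% c("B", "C")
  m <- fit_oplsda(autoscale(tab$concentrations[sel, ]), g[sel], n_orthogonal = 2)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-8)
  expect_equal(sum(m$vip^2), 26, tolerance = 1e-8)
  for (j in seq_len(ncol(m$orthogonal_scores)))
    expect_lt(abs(sum(m$predictive_scores * m$orthogonal_scores[, j])), 1e-8)
  expect_error(fit_oplsda(autoscale(tab$concentrations), rep("B", sum(sel))),
               "2 classes")
})

test_that("a single separating variable attains the maximal VIP", {
  set.seed(7)
  n <- 20
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 5), n, 5)
  X[, 3] <- ifelse(y == "a", 0, 1) + rnorm(n, sd = 1e-3)  # carries all separation
  m <- fit_oplsda(autoscale(X), y, n_orthogonal = 0)
  expect_equal(which.max(m$vip), 3)
  expect_gt(m$vip[3], 1.5)                # weight concentrates on one variable
})

test_that("OPLS-DA with zero orthogonal components equals one-component PLS1", {
  skip_if_not_installed("mixOmics")
  set.seed(8)
  X <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rep(c("a", "b"), 5)
  Xc <- sweep(X, 2, colMeans(X))
  m <- fit_oplsda(Xc, y, n_orthogonal = 0)
  yy <- ifelse(y == "b", 1, -1)
  pls <- mixOmics::pls(Xc, matrix(yy), ncomp = 1, mode = "regression",
                       scale = FALSE)
  t_or <- pls$variates$X[, 1]
  t_or <- t_or - mean(t_or)
  # same latent direction up to sign, to numerical precision
  s <- sign(sum(t_or * m$predictive_scores))
  expect_equal(unname(s * t_or / sqrt(sum(t_or^2))),
               unname(m$predictive_scores / sqrt(sum(m$predictive_scores^2))),
               tolerance = 1e-8)
  # identical fitted class scores
  fitted_mine <- mean(yy) + m$core$c_p * m$core$t_p
  fitted_pls <- drop(stats::predict(pls, Xc)$predict[, 1, 1])
  expect_equal(unname(fitted_mine), unname(fitted_pls), tolerance = 1e-8)
})

test_that("permutation test validates separable data and rejects noise", {
  tab <- generate_compound_table(synthetic_config(seed = 9))
  g <- attr(tab, "group"); sel <- g %in% c("B", "C")
  rep_good <- permutation_test(autoscale(tab$concentrations[sel, ]), g[sel],
                               n_permutations = 60, seed = 2)
  expect_true(rep_good$valid)
  expect_lt(rep_good$q2_intercept, 0)
  expect_length(rep_good$permuted_q2, 60)

  set.seed(10)
  N <- matrix(rnorm(38 * 26), 38, 26)
  rep_bad <- permutation_test(autoscale(N), g[sel], n_permutations = 60, seed = 2)
  expect_false(rep_bad$valid)
})
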
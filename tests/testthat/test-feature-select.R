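test_that("pooled t map matches a textbook hand computation", {
  dims <- c(2, 1, 1)
  m <- full_mask(dims)
  g0 <- c(1.0, 1.2, 0.8); g1 <- c(2.0, 2.4, 1.9)
  mk <- function(v) array(c(v, 0), dims)
  tm <- two_sample_t_map(lapply(g0, mk), lapply(g1, mk), m)
  # independent formula oracle
  sp <- sqrt(((length(g0) - 1) * var(g0) + (length(g1) - 1) * var(g1)) / 4)
  t_hand <- (mean(g0) - mean(g1)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(tm$t[1, 1, 1], t_hand, tolerance = 1e-12)
  expect_equal(tm$df, 4)
  # cross-check against stats::t.test with pooled variance
  tt <- t.test(g0, g1, var.equal = TRUE)
  expect_equal(tm$t[1, 1, 1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(tm$p[1, 1, 1], tt$p.value, tolerance = 1e-12)
  # zero-variance voxel: t = 0, p = 1, flagged
  expect_equal(tm$t[2, 1, 1], 0)
  expect_equal(tm$p[2, 1, 1], 1)
  expect_equal(tm$n_zero_variance, 1)
})

test_that("t map is antisymmetric under group exchange", {
  set.seed(31)
  dims <- c(4, 4, 2)
  m <- full_mask(dims)
  g0 <- lapply(1:4, function(i) array(rnorm(prod(dims)), dims))
  g1 <- lapply(1:5, function(i) array(rnorm(prod(dims)), dims))
  a <- two_sample_t_map(g0, g1, m)
  b <- two_sample_t_map(g1, g0, m)
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("cluster labelling matches the flood-fill oracle", {
  set.seed(32)
  for (conn in c(6, 18, 26)) {
    blob <- array(runif(6 * 6 * 6) < 0.35, c(6, 6, 6))
    ours <- label_clusters(blob, conn)
    oracle <- flood_fill_labels(blob, conn)
    expect_true(same_partition(ours, oracle))
  }
})

test_that("cluster extent filter drops small components and is idempotent", {
  a <- array(0, c(10, 10, 10))
  a[1:84] <- 1                      # one 84-voxel component (column-major)
  expect_equal(sum(cluster_extent_filter(a, 85)), 0)
  expect_equal(sum(cluster_extent_filter(a, 84)), 84)
  # empty input -> empty output
  expect_equal(sum(cluster_extent_filter(array(0, c(4, 4, 4)), 2)), 0)
  # idempotence
  set.seed(33)
  blob <- array(runif(8^3) < 0.3, c(8, 8, 8))
  once <- cluster_extent_filter(blob, 4)
  twice <- cluster_extent_filter(once, 4)
  expect_identical(once, twice)
})

test_that("Monte-Carlo cluster threshold behaves in limiting regimes", {
  m <- mask_volume(array(TRUE, c(8, 8, 8)))
  # fwhm 0, alpha 0.001: near-independent voxels, tiny clusters
  s0 <- alphasim_min_cluster(m, 0, c(3, 3, 3), 0.001, 0.05,
                             n_iter = 1000, seed = 42)
  expect_true(s0 %in% c(1L, 2L))
  # smoothing can only raise the required extent
  s6 <- alphasim_min_cluster(m, 6, c(3, 3, 3), 0.001, 0.05,
                             n_iter = 200, seed = 42)
  expect_gte(s6, s0)
  # unresolvable cluster alpha
  expect_error(alphasim_min_cluster(m, 0, c(3, 3, 3), 0.05, 0.001,
                                    n_iter = 100), "unresolvable")
})

test_that("univariate mask keeps per-measure voxels and unions them", {
  dims <- c(6, 6, 6)
  m <- full_mask(dims)
  set.seed(34)
  mk_group <- function(n, bump_at = NULL, delta = 0) {
    lapply(seq_len(n), function(i) {
      a <- array(rnorm(prod(dims), sd = 0.2), dims)
      if (!is.null(bump_at)) a[bump_at] <- a[bump_at] + delta
      a
    })
  }
  idx_a <- 1:8; idx_b <- 100:107
  tA <- two_sample_t_map(mk_group(6), mk_group(6, idx_a, 3), m)
  tB <- two_sample_t_map(mk_group(6), mk_group(6, idx_b, 3), m)
  um <- univariate_mask(list(A = tA, B = tB), alpha_voxel = 0.001,
                        min_cluster_voxels = 1)
  expect_true(all(idx_a %in% which(um$masks$A)))
  expect_true(all(idx_b %in% which(um$masks$B)))
  # disjoint significant sets concatenate to their disjoint union
  maps <- list(s1 = list(A = mk_group(1)[[1]], B = mk_group(1)[[1]]),
               s2 = list(A = mk_group(1)[[1]], B = mk_group(1)[[1]]))
  fm <- build_feature_matrix(maps, um$masks, c(0, 1))
  expect_equal(ncol(fm$values), sum(um$report$n_voxels))
  # all-empty masks advise a larger alpha
  t0 <- two_sample_t_map(mk_group(3), mk_group(3), m)
  expect_error(univariate_mask(list(A = t0), alpha_voxel = 1e-12),
               "larger alpha")
})

test_that("SVM-RFE ranks a separating feature first, deterministically", {
  set.seed(35)
  n <- 24
  X <- cbind(rep(c(-2, 2), each = n / 2) + rnorm(n, sd = 0.3),
             matrix(rnorm(n * 6), n, 6))
  X <- scale(X)
  y <- rep(c(0, 1), each = n / 2)
  r <- svm_rfe_rank(X, y)
  expect_equal(r$ranking[1], 1L)    # eliminated last
  # duplicated columns: tie broken by index, bitwise repeatable
  Xd <- cbind(X[, 1], X[, 1], X[, 2])
  r1 <- svm_rfe_rank(Xd, y); r2 <- svm_rfe_rank(Xd, y)
  expect_identical(r1$ranking, r2$ranking)
  # equal weights tie: the lower column index is eliminated first, so
  # column 1 carries the worse (larger) rank than its duplicate
  expect_gt(r1$ranking[1], r1$ranking[2])
})

test_that("RFE first elimination matches the analytic hard-margin SVM", {
  # 4 points, separable along x1 with margin 2, along x2 with margin 4:
  # hard-margin w = (1, 0.?) -> smaller |w| on the wider-margin feature
  X <- rbind(c(-1, -2), c(-1, 2), c(1, -2), c(1, 2))
  y <- c(0, 0, 1, 1)
  # analytic: w = (1, 0); feature 2 has zero weight and is eliminated first
  r <- svm_rfe_rank(X, y, cost = 1e3)
  expect_equal(r$elimination_order[1], 2L)
  expect_equal(r$ranking, c(1L, 2L))
})

test_that("rfe_select_k recovers informative features and handles edges", {
  set.seed(36)
  n <- 40; q <- 40
  X <- matrix(rnorm(n * q), n, q)
  y <- rep(c(0, 1), each = n / 2)
  X[, 1:10] <- X[, 1:10] + outer(ifelse(y == 1, 0.7, -0.7), rep(1, 10))
  X <- scale(X)
  rk <- svm_rfe_rank(X, y)
  sel <- rfe_select_k(X, y, rk$ranking, k_grid = c(5, 10, 20, 30), seed = 4)
  expect_true(length(sel$kept) %in% c(5, 10, 20, 30))
  expect_gte(mean(1:10 %in% sel$kept), 0.8)
  # k_grid = {q} is the identity selection
  sel_all <- rfe_select_k(X, y, rk$ranking, k_grid = q, seed = 4)
  expect_equal(sort(sel_all$kept), 1:q)
  expect_error(rfe_select_k(X, y, rk$ranking, k_grid = integer(0)),
               "empty k_grid")
})

test_that("lasso limits: OLS at lambda 0, all-zero at lambda_max, 1-D", {
  set.seed(37)
  X <- matrix(rnorm(80), 20, 4)
  y <- as.numeric(X %*% c(1, -2, 0.5, 0) + rnorm(20, sd = 0.1))
  f0 <- lasso_path(X, y, lambda = 1e-12, standardize = FALSE)
  ols <- unname(coef(lm(y ~ X)))
  expect_lt(max(abs(f0$gamma[, 1] - ols[-1])), 1e-6)
  expect_lt(abs(f0$gamma0[1] - ols[1]), 1e-6)
  # lambda >= lambda_max: every coefficient exactly zero
  n <- nrow(X)
  lam_max <- max(abs(crossprod(sweep(X, 2, colMeans(X)), y - mean(y)))) / n
  fmax <- lasso_path(X, y, lambda = lam_max * (1 + 1e-9),
                     standardize = FALSE)
  expect_true(all(fmax$gamma == 0))
  # single standardized feature: soft-threshold closed form
  x1 <- scale(X[, 1]) * sqrt(n / (n - 1))     # exactly unit 1/n variance
  yc <- y - mean(y)
  for (lam in c(0.05, 0.2, 0.8)) {
    rho <- sum(x1 * yc) / n
    expected <- sign(rho) * max(abs(rho) - lam, 0) / (sum(x1^2) / n)
    f1 <- lasso_path(matrix(x1), y, lambda = lam, standardize = FALSE)
    expect_equal(f1$gamma[1, 1], expected, tolerance = 1e-8)
  }
})

test_that("lasso path sparsity is monotone and matches glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(38)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- as.numeric(X[, 1] - 1.5 * X[, 2] + rnorm(40, sd = 0.5))
  lam <- exp(seq(log(0.8), log(0.005), length.out = 12))
  f <- lasso_path(X, y, lambda = lam, standardize = FALSE)
  nz <- colSums(f$gamma != 0)
  expect_true(all(diff(nz) >= 0))   # lambda decreasing -> support grows
  g <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                      thresh = 1e-12)
  expect_lt(max(abs(as.matrix(g$beta) - f$gamma)), 1e-4)
})

test_that("lasso_select picks the CV-MSE-minimising lambda", {
  set.seed(39)
  n <- 40
  X <- matrix(rnorm(n * 12), n, 12)
  y <- rep(c(0, 1), each = n / 2)
  X[, 1:3] <- X[, 1:3] + outer(ifelse(y == 1, 1.5, -1.5), rep(1, 3))
  out <- lasso_select(X, y, seed = 9)
  expect_s3_class(out$fit, "lasso_fit")
  expect_equal(out$fit$lambda_opt,
               out$fit$cv_mse$lambda[which.min(out$fit$cv_mse$mse)])
  expect_gte(mean(1:3 %in% out$selection$kept), 2 / 3)
  expect_true(all(out$selection$kept %in% seq_len(ncol(X))))
})

test_that("selection uses training rows only (no test-row leakage)", {
  set.seed(40)
  n <- 24; q <- 15
  X <- matrix(rnorm(n * q), n, q)
  y <- rep(c(0, 1), n / 2)
  X[, 1] <- X[, 1] + ifelse(y == 1, 2, -2)
  train <- 1:16; test <- 17:24
  run_sel <- function(Xfull) {
    Xtr <- scale(Xfull[train, ])
    rk <- svm_rfe_rank(Xtr, y[train])
    sel <- rfe_select_k(Xtr, y[train], rk$ranking, k_grid = c(2, 5, 10),
                        seed = 2)
    list(rank = rk$ranking, kept = sel$kept)
  }
  a <- run_sel(X)
  Xperturbed <- X
  Xperturbed[test, ] <- matrix(rnorm(length(test) * q, sd = 50),
                               length(test), q)
  b <- run_sel(Xperturbed)
  expect_identical(a$rank, b$rank)
  expect_identical(a$kept, b$kept)
})
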
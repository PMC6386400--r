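# Training-data-only feature reduction: voxelwise two-sample t maps with
# cluster-extent Monte-Carlo correction, then SVM recursive feature
# elimination or LASSO on the concatenated surviving features.

#' Critical two-tailed Student t value
#'
#' @param alpha two-tailed significance level.
#' @param df degrees of freedom.
#' @return `qt(1 - alpha/2, df)`.
#' @export
critical_t <- function(alpha, df) qt(1 - alpha / 2, df)

#' Voxelwise pooled-variance two-sample t map
#'
#' Student t with pooled variance per in-mask voxel, two-tailed p from the
#' t distribution at `n0 + n1 - 2` degrees of freedom. Voxels with zero
#' pooled variance get t = 0, p = 1 and are counted in the result.
#'
#' @param maps_group0,maps_group1 lists of 3-D arrays (one per subject).
#' @param mask the brain [mask_volume()].
#' @return An object of class `t_test_map`: list with 3-D arrays `t` and
#'   `p`, scalar `df`, and `n_zero_variance`.
#' @export
two_sample_t_map <- function(maps_group0, maps_group1, mask) {
  n0 <- length(maps_group0); n1 <- length(maps_group1)
  if (n0 < 2 || n1 < 2) stop("need at least 2 subjects per group")
  dims <- dim(mask$data)
  vox <- which(mask$data)
  stack <- function(maps) {
    for (m in maps) if (!all(dim(m) == dims)) stop("map dims differ from mask")
    vapply(maps, function(m) as.numeric(m)[vox], numeric(length(vox)))
  }
  X0 <- stack(maps_group0); X1 <- stack(maps_group1)
  m0 <- rowMeans(X0); m1 <- rowMeans(X1)
  v0 <- rowSums((X0 - m0)^2); v1 <- rowSums((X1 - m1)^2)
  df <- n0 + n1 - 2
  sp2 <- (v0 + v1) / df
  se <- sqrt(sp2 * (1 / n0 + 1 / n1))
  zero <- se == 0
  tval <- ifelse(zero, 0, (m0 - m1) / ifelse(zero, 1, se))
  pval <- ifelse(zero, 1, 2 * pt(-abs(tval), df))
  t_arr <- array(0, dim = dims); t_arr[vox] <- tval
  p_arr <- array(1, dim = dims); p_arr[vox] <- pval
  structure(list(t = t_arr, p = p_arr, df = df,
                 n_zero_variance = sum(zero), mask = mask),
            class = "t_test_map")
}

#' @export
print.t_test_map <- function(x, ...) {
  cat(sprintf("<t_test_map> df = %d, |t| range %.3f-%.3f over %d voxels\n",
              x$df, min(abs(x$t[x$mask$data])), max(abs(x$t[x$mask$data])),
              sum(x$mask$data)))
  invisible(x)
}

connectivity_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  d <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  switch(as.character(connectivity),
         "6"  = g[d == 1, ],
         "18" = g[d <= 2, ],
         "26" = g,
         stop("connectivity must be one of 6, 18, 26"))
}

#' Label connected components of a binary 3-D map
#'
#' Voxels are connected under the chosen neighbourhood (6 faces, 18
#' faces+edges, 26 faces+edges+corners). Component ids are assigned in
#' first-voxel (column-major) order.
#'
#' @param binary logical/0-1 3-D array.
#' @param connectivity 6, 18 or 26 (default).
#' @return Integer 3-D array of component labels (0 = background).
#' @export
label_clusters <- function(binary, connectivity = 26) {
  dims <- dim(binary)
  stopifnot(length(dims) == 3L)
  vox <- which(binary != 0)
  out <- array(0L, dim = dims)
  if (!length(vox)) return(out)
  idx_of <- integer(prod(dims)); idx_of[vox] <- seq_along(vox)
  coord <- arrayInd(vox, dims)
  off <- connectivity_offsets(connectivity)
  edges <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    nb <- sweep(coord, 2, c(off$dx[r], off$dy[r], off$dz[r]), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] +
      (nb[ok, 3] - 1) * dims[1] * dims[2]
    hit <- idx_of[lin] > 0
    if (any(hit))
      edges[[r]] <- cbind(which(ok)[hit], idx_of[lin[hit]])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    rbind(matrix(rep(seq_along(vox), 2), ncol = 2), edges),
    directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(vox)]
  relabel <- match(comp, unique(comp))   # ids in first-voxel order
  out[vox] <- relabel
  out
}

#' Remove clusters smaller than a minimum extent
#'
#' Connected components of the supra-threshold map with fewer than
#' `min_cluster_voxels` voxels are removed; the operation is idempotent.
#'
#' @param binary logical/0-1 3-D array.
#' @param min_cluster_voxels minimum surviving component size (>= 1).
#' @param connectivity 6, 18 or 26.
#' @return Logical 3-D array.
#' @export
cluster_extent_filter <- function(binary, min_cluster_voxels,
                                  connectivity = 26) {
  stopifnot(min_cluster_voxels >= 1)
  lab <- label_clusters(binary, connectivity)
  if (!any(lab > 0)) return(array(FALSE, dim = dim(lab)))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_cluster_voxels)
  array(lab %in% keep, dim = dim(lab))
}

#' Monte-Carlo minimum cluster size (AlphaSim-style)
#'
#' Simulates `n_iter` Gaussian white-noise volumes, smooths each to the
#' given FWHM, re-standardises within the mask, thresholds two-tailed at
#' `alpha_voxel` (|z| criterion), and records the maximum supra-threshold
#' cluster size per iteration. Returns the smallest size `s` with
#' `P(max cluster >= s) <= alpha_cluster`.
#'
#' @param mask the brain [mask_volume()].
#' @param fwhm_mm smoothing FWHM in mm (0 = unsmoothed noise).
#' @param voxel_size_mm voxel size in mm.
#' @param alpha_voxel voxelwise two-tailed alpha.
#' @param alpha_cluster cluster-level alpha; must be >= 1/n_iter.
#' @param n_iter Monte-Carlo iterations (default 1000).
#' @param connectivity cluster connectivity.
#' @param seed RNG seed.
#' @return Integer minimum cluster extent in voxels.
#' @export
alphasim_min_cluster <- function(mask, fwhm_mm, voxel_size_mm, alpha_voxel,
                                 alpha_cluster, n_iter = 1000,
                                 connectivity = 26, seed = 1L) {
  stopifnot(n_iter >= 1)
  if (alpha_cluster < 1 / n_iter)
    stop("alpha_cluster below 1/n_iter is unresolvable; raise n_iter")
  dims <- dim(mask$data)
  zcrit <- qnorm(1 - alpha_voxel / 2)
  maxima <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      noise <- array(rnorm(prod(dims)), dim = dims)
      if (fwhm_mm > 0)
        noise <- smooth_gaussian(noise, fwhm_mm, voxel_size_mm)
      v <- noise[mask$data]
      v <- (v - mean(v)) / sd(v)
      supra <- array(FALSE, dim = dims)
      supra[mask$data] <- abs(v) > zcrit
      if (!any(supra)) return(0L)
      max(tabulate(label_clusters(supra, connectivity)))
    }, integer(1))
  })
  smax <- max(maxima, 1L)
  for (s in seq_len(smax)) {
    if (mean(maxima >= s) <= alpha_cluster) return(as.integer(s))
  }
  as.integer(smax + 1L)
}

#' Per-measure univariate selection masks
#'
#' For each measure's training t map: threshold `|t| >= critical_t(alpha,
#' df)`, then apply the cluster-extent filter. Concatenation keeps each
#' measure's own surviving voxels.
#'
#' @param t_maps named list of [two_sample_t_map()] results (one per
#'   measure).
#' @param alpha_voxel voxelwise two-tailed alpha.
#' @param min_cluster_voxels minimum cluster extent (1 disables the filter).
#' @param connectivity cluster connectivity.
#' @return List with `masks` (named list of logical arrays) and `report`
#'   tibble (measure, critical_t, n_voxels). Errors if every mask is empty.
#' @export
univariate_mask <- function(t_maps, alpha_voxel = 0.05,
                            min_cluster_voxels = 1, connectivity = 26) {
  stopifnot(length(t_maps) >= 1)
  masks <- list(); rows <- list()
  for (nm in names(t_maps)) {
    tm <- t_maps[[nm]]
    tc <- critical_t(alpha_voxel, tm$df)
    supra <- abs(tm$t) >= tc & tm$mask$data
    if (min_cluster_voxels > 1)
      supra <- cluster_extent_filter(supra, min_cluster_voxels, connectivity)
    masks[[nm]] <- supra
    rows[[nm]] <- tibble::tibble(measure = nm, critical_t = tc,
                                 n_voxels = sum(supra))
  }
  report <- dplyr::bind_rows(rows)
  if (sum(report$n_voxels) == 0)
    stop("no voxels survive the univariate mask in any measure; ",
         "consider a larger alpha_voxel or smaller cluster threshold")
  list(masks = masks, report = report)
}

linear_svm_weights <- function(X, y, cost = 1) {
  fit <- e1071::svm(X, factor(y, levels = sort(unique(y))),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  # e1071 drops unused dimensions never; w has length ncol(X)
  w
}

#' SVM recursive feature elimination ranking
#'
#' Iteratively trains a linear SVM, scores features by the squared weight
#' `w_j^2`, eliminates the lowest-scoring `step` features, and repeats
#' until none remain. The ranking is the reverse elimination order (rank 1
#' = eliminated last = most informative). Ties are broken by eliminating
#' the lower column index first, so runs are deterministic.
#'
#' @param X n x q numeric matrix (standardised features).
#' @param y labels (two classes).
#' @param step features removed per iteration; `"auto"` removes 1 when
#'   q <= 500 and 10% of the remainder otherwise.
#' @param cost linear SVM cost parameter.
#' @return An object of class `selection_result` with fields `ranking`
#'   (integer rank per column), `elimination_order`, `method = "rfe"`.
#' @export
svm_rfe_rank <- function(X, y, step = "auto", cost = 1) {
  q <- ncol(X)
  stopifnot(q >= 2, length(unique(y)) == 2)
  auto <- identical(step, "auto")
  remaining <- seq_len(q)
  eliminated <- integer(0)
  while (length(remaining) > 0) {
    if (length(remaining) == 1L) {
      eliminated <- c(eliminated, remaining)
      break
    }
    w <- tryCatch(
      linear_svm_weights(X[, remaining, drop = FALSE], y, cost = cost),
      error = function(e)
        stop("linear SVM failed with ", length(remaining),
             " features remaining: ", conditionMessage(e)))
    k <- if (auto) {
      if (length(remaining) <= 500) 1L
      else max(1L, floor(length(remaining) * 0.1))
    } else min(step, length(remaining) - 1L)
    ord <- order(w^2, remaining)         # ties: lower column index first
    drop_idx <- ord[seq_len(k)]
    eliminated <- c(eliminated, remaining[drop_idx])
    remaining <- remaining[-drop_idx]
  }
  ranking <- integer(q)
  ranking[rev(eliminated)] <- seq_len(q)   # rank 1 = last eliminated
  structure(list(kept = order(ranking), ranking = ranking,
                 elimination_order = eliminated, method = "rfe",
                 params = list(step = step, cost = cost)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method = %s, %d feature(s) kept\n",
              x$method, length(x$kept)))
  invisible(x)
}

#' Choose the RFE feature count by inner cross-validation
#'
#' For each candidate k, trains a linear SVM on the top-k ranked features
#' and measures stratified inner-CV accuracy; returns the k with the best
#' accuracy (ties go to the smallest k).
#'
#' @param X n x q matrix, `y` labels.
#' @param y labels (two classes).
#' @param ranking integer ranking from [svm_rfe_rank()].
#' @param k_grid candidate feature counts (values > q are capped at q).
#' @param inner_folds stratified fold count.
#' @param cost SVM cost.
#' @param seed fold-assignment seed.
#' @return A `selection_result` with the chosen `kept` set and a
#'   `cv_curve` tibble (k, accuracy).
#' @export
rfe_select_k <- function(X, y, ranking, k_grid, inner_folds = 5, cost = 1,
                         seed = 1L) {
  if (!length(k_grid)) stop("empty k_grid")
  k_grid <- sort(unique(pmin(k_grid, ncol(X))))
  folds <- stratified_folds(y, min(inner_folds, min(table(y))), seed)
  acc <- vapply(k_grid, function(k) {
    top <- order(ranking)[seq_len(k)]
    mean(vapply(seq_len(max(folds)), function(f) {
      tr <- folds != f; te <- !tr
      if (length(unique(y[tr])) < 2) return(NA_real_)
      fit <- e1071::svm(X[tr, top, drop = FALSE],
                        factor(y[tr], levels = sort(unique(y))),
                        kernel = "linear", cost = cost, scale = FALSE)
      mean(predict(fit, X[te, top, drop = FALSE]) == y[te])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- k_grid[which.max(acc)]         # which.max takes the smallest tie
  structure(list(kept = order(ranking)[seq_len(best)], ranking = ranking,
                 method = "rfe", params = list(k = best, cost = cost),
                 cv_curve = tibble::tibble(k = k_grid, accuracy = acc)),
            class = "selection_result")
}

# cyclic coordinate descent for the lasso objective
# (1/2n) * sum((y - g0 - X g)^2) + lambda * sum(|g|)
lasso_cd <- function(X, y, lambda_seq, tol = 1e-9, max_iter = 10000L) {
  n <- nrow(X); q <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  xsq <- colSums(Xc^2) / n
  G <- matrix(0, q, length(lambda_seq))
  g <- numeric(q)
  r <- yc                                   # residual for current g
  for (li in seq_along(lambda_seq)) {
    lam <- lambda_seq[li]
    for (iter in seq_len(max_iter)) {
      delta <- 0
      for (j in seq_len(q)) {
        if (xsq[j] == 0) next
        rho <- sum(Xc[, j] * r) / n + xsq[j] * g[j]
        gj <- sign(rho) * max(abs(rho) - lam, 0) / xsq[j]
        if (gj != g[j]) {
          r <- r - Xc[, j] * (gj - g[j])
          delta <- max(delta, abs(gj - g[j]))
          g[j] <- gj
        }
      }
      if (delta < tol) break
    }
    G[, li] <- g
  }
  gamma0 <- vapply(seq_along(lambda_seq),
                   function(li) ym - sum(xm * G[, li]), numeric(1))
  list(gamma = G, gamma0 = gamma0, lambda = lambda_seq)
}

#' Fit a LASSO path by coordinate descent
#'
#' Minimises `(1/2n) * sum_i (u_i - g0 - x_i' g)^2 + lambda * sum_j |g_j|`
#' by cyclic coordinate descent with warm starts along a decreasing lambda
#' sequence. With `lambda >= lambda_max = max_j |x_j . (u - mean(u))| / n`
#' (centred predictors) all coefficients are zero.
#'
#' @param X n x q matrix; `y` numeric response (group labels 0/1 work).
#' @param y numeric response vector.
#' @param lambda decreasing sequence; `NULL` builds a 50-point log grid
#'   from `lambda_max` down to `0.001 * lambda_max`.
#' @param standardize z-score columns internally (coefficients are
#'   reported on the original scale).
#' @return An object of class `lasso_fit`: `gamma0`, `gamma` (q x
#'   n_lambda), `lambda`, `lambda_max`.
#' @export
lasso_path <- function(X, y, lambda = NULL, standardize = TRUE) {
  stopifnot(all(is.finite(X)), all(is.finite(y)), nrow(X) == length(y))
  st <- if (standardize) standardize_fit(X) else
    list(mean = rep(0, ncol(X)), sd = rep(1, ncol(X)))
  Xs <- standardize_apply(X, st)
  n <- nrow(Xs)
  lam_max <- max(abs(crossprod(sweep(Xs, 2, colMeans(Xs)),
                               y - mean(y)))) / n
  if (is.null(lambda))
    lambda <- exp(seq(log(max(lam_max, 1e-12)),
                      log(max(lam_max, 1e-12) * 1e-3), length.out = 50))
  lambda <- sort(lambda, decreasing = TRUE)
  fit <- lasso_cd(Xs, y, lambda)
  gamma <- fit$gamma / st$sd             # back to original scale
  gamma0 <- vapply(seq_along(lambda), function(li)
    fit$gamma0[li] - sum(st$mean * gamma[, li]), numeric(1))
  structure(list(gamma0 = gamma0, gamma = gamma, lambda = lambda,
                 lambda_max = lam_max), class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> %d lambda values, lambda_max = %.4g\n",
              length(x$lambda), x$lambda_max))
  invisible(x)
}

#' LASSO feature selection with cross-validated lambda
#'
#' Fits the coordinate-descent path, picks the lambda minimising the
#' k-fold cross-validated mean squared error, and keeps the features with
#' nonzero coefficients there. If that set is empty, the single feature
#' with the largest maximal |coefficient| along the path is kept.
#'
#' @param X n x q matrix; `y` 0/1 labels (regressed as numeric response).
#' @param y numeric/0-1 response.
#' @param lambda optional lambda sequence (see [lasso_path()]).
#' @param nfolds CV folds.
#' @param seed fold-assignment seed.
#' @return List with `fit` (a `lasso_fit` carrying `cv_mse` tibble and
#'   `lambda_opt`) and `selection` (a `selection_result`).
#' @export
lasso_select <- function(X, y, lambda = NULL, nfolds = 5, seed = 1L) {
  y <- as.numeric(y)
  fit <- lasso_path(X, y, lambda)
  lambda <- fit$lambda
  folds <- stratified_folds(y, min(nfolds, min(table(y))), seed)
  mse <- matrix(NA_real_, max(folds), length(lambda))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    pf <- lasso_path(X[tr, , drop = FALSE], y[tr], lambda)
    pred <- cbind(1, X[!tr, , drop = FALSE]) %*% rbind(pf$gamma0, pf$gamma)
    mse[f, ] <- colMeans((pred - y[!tr])^2)
  }
  cv_mse <- colMeans(mse)
  li <- which.min(cv_mse)
  kept <- which(fit$gamma[, li] != 0)
  if (!length(kept))
    kept <- which.max(apply(abs(fit$gamma), 1, max))
  fit$cv_mse <- tibble::tibble(lambda = lambda, mse = cv_mse)
  fit$lambda_opt <- lambda[li]
  sel <- structure(list(kept = kept,
                        ranking = rank(-abs(fit$gamma[, li]),
                                       ties.method = "first"),
                        method = "lasso",
                        params = list(lambda = lambda[li], nfolds = nfolds)),
                   class = "selection_result")
  list(fit = fit, selection = sel)
}
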
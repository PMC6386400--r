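# Extreme learning machine (single hidden layer, random fixed input
# weights, output weights by a single pseudoinverse solve) plus linear/RBF
# SVM baselines with exhaustive grid search.

#' Train an extreme learning machine
#'
#' Input weights and biases are drawn Uniform(-1, 1) from `seed`; the
#' hidden activation is the standard sigmoid `1/(1 + exp(-z))`; the output
#' weights solve `H beta = y` in the least-squares sense via the
#' Moore-Penrose pseudoinverse (no iteration, deterministic given the
#' seed). Binary targets are coded -1/+1.
#'
#' @param X n x d feature matrix.
#' @param y labels: -1/+1, 0/1, or a two-level factor.
#' @param L hidden-node count (>= 1).
#' @param seed initialisation seed.
#' @param ridge optional ridge term added to the normal equations for
#'   ill-conditioned hidden layers (0 = pure pseudoinverse, the default).
#' @return An object of class `elm_model`.
#' @export
elm_train <- function(X, y, L, seed = 1L, ridge = 0) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, L >= 1)
  y <- elm_targets(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  d <- ncol(X)
  init <- with_seed(seed, list(
    W = matrix(runif(L * d, -1, 1), L, d),
    b = runif(L, -1, 1)))
  H <- sigmoid(X %*% t(init$W) + rep(init$b, each = nrow(X)))
  beta <- if (ridge > 0) {
    solve(crossprod(H) + diag(ridge, L), crossprod(H, y))
  } else {
    pinv_solve(H, y)
  }
  structure(list(input_weights = init$W, biases = init$b,
                 output_weights = as.numeric(beta), L = L,
                 activation = "sigmoid", seed = seed, d = d),
            class = "elm_model")
}

elm_targets <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  u <- sort(unique(y))
  if (all(u %in% c(-1, 1))) return(as.numeric(y))
  if (all(u %in% c(0, 1))) return(ifelse(y == 1, 1, -1))
  stop("labels must be binary (-1/+1, 0/1, or a two-level factor)")
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d hidden nodes, %d inputs, sigmoid activation\n",
              x$L, x$d))
  invisible(x)
}

#' Predict labels with a trained ELM
#'
#' Decision is `sign(H beta)` with the tie `sign(0)` mapped to +1.
#'
#' @param model an [elm_train()] fit.
#' @param X n x d matrix with d matching the training data.
#' @return Numeric vector of -1/+1 labels.
#' @export
elm_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    stop("feature count ", ncol(X), " does not match model (", model$d, ")")
  H <- sigmoid(X %*% t(model$input_weights) +
                 rep(model$biases, each = nrow(X)))
  score <- as.numeric(H %*% model$output_weights)
  ifelse(score >= 0, 1, -1)
}

#' Grid-search the ELM hidden-layer size
#'
#' For each candidate L, the stratified inner-CV validation accuracy is
#' averaged over `n_repeats` random initialisations (100 by default,
#' damping initialisation noise); the L with the highest mean accuracy
#' wins, ties going to the smallest L.
#'
#' @param X n x d matrix; `y` binary labels.
#' @param y binary labels.
#' @param L_grid candidate hidden-node counts (default 1:400).
#' @param n_repeats random initialisations averaged per L.
#' @param inner_folds stratified fold count.
#' @param seed master seed (fold assignment + initialisation substreams).
#' @return List with `best_L`, `accuracy` (its mean validation accuracy)
#'   and `curve` tibble (L, accuracy).
#' @export
elm_grid_search <- function(X, y, L_grid = 1:400, n_repeats = 100,
                            inner_folds = 5, seed = 1L) {
  stopifnot(length(L_grid) >= 1)
  L_grid <- sort(unique(L_grid))         # ascending, so ties pick smallest L
  y01 <- as.integer(elm_targets(y) > 0)
  folds <- stratified_folds(y01, min(inner_folds, min(table(y01))),
                            substream_seed(seed, "elm_folds"))
  acc <- vapply(seq_along(L_grid), function(gi) {
    L <- L_grid[gi]
    mean(vapply(seq_len(n_repeats), function(rep_i) {
      init_seed <- substream_seed(seed, "elm_init", gi * 100000L + rep_i)
      mean(vapply(seq_len(max(folds)), function(f) {
        tr <- folds != f
        if (length(unique(y01[tr])) < 2) return(NA_real_)
        fit <- elm_train(X[tr, , drop = FALSE], y01[tr], L, init_seed)
        pred <- elm_predict(fit, X[!tr, , drop = FALSE])
        mean((pred > 0) == (y01[!tr] == 1))
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(acc)                  # smallest L on ties
  list(best_L = L_grid[best], accuracy = acc[best],
       curve = tibble::tibble(L = L_grid, accuracy = acc))
}

#' Grid-search SVM hyperparameters
#'
#' Exhaustive search over the C grid (and gamma grid for the RBF kernel)
#' maximising stratified inner-CV accuracy; ties go to the smallest C,
#' then the smallest gamma. The default grids are the eight decades
#' 0.001 ... 10000.
#'
#' @param X n x d matrix; `y` binary labels.
#' @param y binary labels.
#' @param kernel `"linear"` or `"radial"`.
#' @param C_grid positive cost grid.
#' @param gamma_grid positive RBF width grid (ignored for linear).
#' @param inner_folds stratified fold count.
#' @param seed fold-assignment seed.
#' @return List with `model` (e1071 fit on all rows at the best setting),
#'   `best` (C, gamma, accuracy) and `curve` tibble.
#' @export
svm_grid_search <- function(X, y, kernel = c("linear", "radial"),
                            C_grid = 10^(-3:4), gamma_grid = 10^(-3:4),
                            inner_folds = 5, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(all(C_grid > 0), all(gamma_grid > 0), all(is.finite(X)))
  yf <- factor(y, levels = sort(unique(y)))
  grid <- if (kernel == "linear") {
    expand.grid(C = sort(C_grid), gamma = NA_real_)
  } else {
    expand.grid(gamma = sort(gamma_grid), C = sort(C_grid))[, c("C", "gamma")]
  }
  grid <- grid[order(grid$C, grid$gamma), ]
  folds <- stratified_folds(as.integer(yf) - 1L,
                            min(inner_folds, min(table(yf))), seed)
  fit_one <- function(tr_x, tr_y, C, gamma)
    if (kernel == "linear")
      e1071::svm(tr_x, tr_y, kernel = "linear", cost = C, scale = FALSE)
    else
      e1071::svm(tr_x, tr_y, kernel = "radial", cost = C, gamma = gamma,
                 scale = FALSE)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    mean(vapply(seq_len(max(folds)), function(f) {
      tr <- folds != f
      if (length(unique(yf[tr])) < 2) return(NA_real_)
      fit <- fit_one(X[tr, , drop = FALSE], yf[tr],
                     grid$C[i], grid$gamma[i])
      mean(predict(fit, X[!tr, , drop = FALSE]) == yf[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- which.max(acc)                  # grid sorted: smallest C, gamma
  model <- fit_one(X, yf, grid$C[best], grid$gamma[best])
  list(model = model,
       best = list(C = grid$C[best], gamma = grid$gamma[best],
                   accuracy = acc[best]),
       curve = tibble::as_tibble(cbind(grid, accuracy = acc)))
}
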
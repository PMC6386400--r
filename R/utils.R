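#' @importFrom stats qt pt sd cor fft mvfft rnorm runif var qnorm quantile
#' @importFrom utils head write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named substream seed from a master seed
#'
#' Every source of randomness in the package draws its seed from a single
#' master seed through a named substream, so that independent stages (cohort
#' generation, ELM initialisation, fold splitting, permutations, cluster-size
#' simulation) are decoupled but jointly reproducible.
#'
#' @param master integer master seed.
#' @param stream character stream name, e.g. `"cohort"`, `"elm"`.
#' @param index optional non-negative integer for per-item substreams
#'   (e.g. one per subject or per repeat).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  s <- (abs(master) %% 1000003) * 10007 + h * 97 + as.integer(index) * 131071
  as.integer(s %% 2147483546L + 1L)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# FWHM -> Gaussian sigma in voxel units (per axis)
fwhm_to_sigma_vox <- function(fwhm_mm, voxel_size_mm) {
  fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))
}

# column-wise z-scoring with training statistics; zero-variance columns are
# centred only (scale 1) so test data never divides by zero
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  list(mean = mu, sd = sigma)
}

standardize_apply <- function(X, stats) {
  sweep(sweep(X, 2, stats$mean, "-"), 2, stats$sd, "/")
}

# stratified k-fold assignment, deterministic given seed
stratified_folds <- function(labels, k, seed) {
  stopifnot(k >= 2)
  fold <- integer(length(labels))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (g in unique(labels)) {
    idx <- which(labels == g)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(code)
}

# minimum-norm least squares via SVD (Moore-Penrose solve of A x = b)
pinv_solve <- function(A, b, tol = NULL) {
  sv <- svd(A)
  tol <- tol %||% (max(dim(A)) * max(sv$d) * .Machine$double.eps)
  pos <- sv$d > tol
  if (!any(pos)) return(rep(0, ncol(A)))
  sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
}
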
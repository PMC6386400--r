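# Voxel-wise measure maps: regional homogeneity (Kendall's W), (fractional)
# amplitude of low-frequency fluctuation, weighted degree centrality, and
# seed-based functional connectivity, plus their concatenation into a
# subjects x features matrix.

#' Kendall's coefficient of concordance over a block of time series
#'
#' Ranks each series over time (mid-ranks on ties, no tie correction — ties
#' have measure zero on continuous data), forms per-time-point rank sums
#' R_i, and returns
#' `W = 12 * sum((R_i - mean(R))^2) / (K^2 * (T^3 - T))`,
#' the classical concordance statistic in `[0, 1]`.
#'
#' @param block K x T numeric matrix: K series (voxels), T time points.
#' @return Scalar W in `[0, 1]`.
#' @export
kcc <- function(block) {
  block <- as.matrix(block)
  K <- nrow(block); n_time <- ncol(block)
  if (K < 2) stop("need at least K = 2 series")
  if (n_time < 2) stop("need at least T = 2 time points")
  ranks <- t(apply(block, 1, rank))      # K x T, mid-ranks for ties
  R <- colSums(ranks)                    # rank sum per time point
  W <- 12 * sum((R - mean(R))^2) / (K^2 * (n_time^3 - n_time))
  min(max(W, 0), 1)
}

neighborhood_offsets <- function(neighborhood) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  switch(as.character(neighborhood),
         "7"  = g[d <= 1, ],
         "19" = g[d <= 2, ],
         "27" = g,
         stop("neighborhood must be one of 7, 19, 27"))
}

#' Regional homogeneity map
#'
#' Per in-mask voxel, Kendall's W of the voxel's series with its in-mask
#' neighbours under the chosen connectivity (27 = the voxel plus its 26
#' neighbours, the default). By default edge voxels use whatever neighbours
#' are in-mask (K adjusted); `strict = TRUE` instead assigns 0 to voxels
#' without a complete neighbourhood, matching toolchains that require it.
#'
#' @param bold preprocessed [bold4d()].
#' @param mask the brain [mask_volume()].
#' @param neighborhood 7, 19 or 27.
#' @param strict require the full neighbourhood.
#' @return 3-D array (class `measure_map`) with attribute `measure = "ReHo"`.
#' @export
reho_map <- function(bold, mask, neighborhood = 27, strict = FALSE) {
  off <- neighborhood_offsets(neighborhood)
  dims <- dim(bold$data)[1:3]
  n_time <- dim(bold$data)[4]
  vox <- which(mask$data)
  Y <- bold_matrix(bold, mask)           # T x V
  ranks <- apply(Y, 2, rank)             # T x V
  # accumulate rank sums and neighbour counts by shifting the rank volume
  rank_vol <- array(0, dim = c(dims, n_time))
  flat <- matrix(rank_vol, nrow = prod(dims))
  flat[vox, ] <- t(ranks)
  rank_vol <- array(flat, dim = c(dims, n_time))
  in_vol <- array(0, dim = dims); in_vol[vox] <- 1

  S <- array(0, dim = c(dims, n_time))   # rank sums over neighbourhood
  Kv <- array(0, dim = dims)             # neighbours present
  for (r in seq_len(nrow(off))) {
    sx <- shift_array(rank_vol, off$dx[r], off$dy[r], off$dz[r])
    S <- S + sx
    Kv <- Kv + shift_array3(in_vol, off$dx[r], off$dy[r], off$dz[r])
  }
  Smat <- matrix(S, nrow = prod(dims))[vox, , drop = FALSE]  # V x T
  K <- Kv[vox]
  Rbar <- K * (n_time + 1) / 2
  ss <- rowSums((Smat - Rbar)^2)
  W <- 12 * ss / (K^2 * (n_time^3 - n_time))
  W[K < 2] <- 0
  if (strict) W[K < neighborhood] <- 0
  out <- array(0, dim = dims)
  out[vox] <- pmin(pmax(W, 0), 1)
  measure_map(out, "ReHo", bold$subject_id)
}

# shift a 4-D array spatially by (dx, dy, dz), zero-filled
shift_array <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, dim = d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  xd <- xs + dx; yd <- ys + dy; zd <- zs + dz
  okx <- xd >= 1 & xd <= d[1]; oky <- yd >= 1 & yd <= d[2]
  okz <- zd >= 1 & zd <= d[3]
  out[xs[okx], ys[oky], zs[okz], ] <-
    a[xd[okx], yd[oky], zd[okz], , drop = FALSE]
  out
}

shift_array3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, dim = d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  xd <- xs + dx; yd <- ys + dy; zd <- zs + dz
  okx <- xd >= 1 & xd <= d[1]; oky <- yd >= 1 & yd <= d[2]
  okz <- zd >= 1 & zd <= d[3]
  out[xs[okx], ys[oky], zs[okz]] <-
    a[xd[okx], yd[oky], zd[okz], drop = FALSE]
  out
}

measure_map <- function(arr, name, subject_id = NULL) {
  structure(arr, measure = name, subject_id = subject_id,
            class = c("measure_map", "array"))
}

#' Amplitude of low-frequency fluctuation (ALFF) and fractional ALFF
#'
#' The one-sided amplitude spectrum `a(f) = sqrt(power)` of each detrended
#' (but NOT band-pass filtered) voxel series is computed by FFT. ALFF is
#' the mean of `a(f)` over the pass-band bins; fALFF is the ratio of the
#' summed band amplitude to the summed full-band amplitude. The full band
#' defaults to (0, Nyquist]: a literal 0.25 Hz cap would exceed the Nyquist
#' frequency at TR = 3 s, but can be requested via `full_band_hz`.
#'
#' @param bold detrended, unfiltered [bold4d()].
#' @param mask the brain [mask_volume()].
#' @param band_hz low-frequency band, default 0.01-0.08 Hz.
#' @param full_band_hz optional length-2 full band; default (0, Nyquist].
#' @return List with elements `alff` and `falff` (`measure_map` arrays).
#'   Voxels with an all-zero spectrum get fALFF 0 and are counted in
#'   attribute `n_zero_spectrum`.
#' @export
alff_falff_map <- function(bold, mask, band_hz = c(0.01, 0.08),
                           full_band_hz = NULL) {
  n_time <- dim(bold$data)[4]
  tr <- bold$tr_s
  nyq <- 1 / (2 * tr)
  full_band_hz <- full_band_hz %||% c(0, nyq)
  freqs <- (seq_len(n_time) - 1) / (n_time * tr)
  half <- 2:(floor(n_time / 2) + 1)                 # exclude DC
  fh <- freqs[half]
  band_bins <- fh >= band_hz[1] & fh <= band_hz[2]
  full_bins <- fh > full_band_hz[1] & fh <= full_band_hz[2]
  if (!any(band_bins)) stop("no FFT bins in the ALFF band")
  Y <- bold_matrix(bold, mask)
  amp <- Mod(mvfft(Y))[half, , drop = FALSE] * (2 / n_time)
  alff_v <- colMeans(amp[band_bins, , drop = FALSE])
  denom <- colSums(amp[full_bins, , drop = FALSE])
  num <- colSums(amp[band_bins, , drop = FALSE])
  zero <- denom == 0
  falff_v <- ifelse(zero, 0, num / pmax(denom, .Machine$double.xmin))
  if (any(zero))
    message(sum(zero), " voxel(s) with zero spectrum; fALFF set to 0")
  dims <- dim(bold$data)[1:3]
  vox <- which(mask$data)
  alff <- array(0, dim = dims); alff[vox] <- alff_v
  falff <- array(0, dim = dims); falff[vox] <- pmin(pmax(falff_v, 0), 1)
  out <- list(alff = measure_map(alff, "ALFF", bold$subject_id),
              falff = measure_map(falff, "fALFF", bold$subject_id))
  attr(out$falff, "n_zero_spectrum") <- sum(zero)
  out
}

#' Weighted degree centrality map
#'
#' Pearson correlation between every pair of in-mask voxel series; each
#' voxel's degree is the sum of the correlations exceeding `r_threshold`
#' (signed threshold: anticorrelations never contribute). The map is then
#' standardised to mean 0, SD 1 over the mask. Constant voxel series get
#' zero correlations with a warning.
#'
#' @param bold preprocessed [bold4d()].
#' @param mask the brain [mask_volume()] (>= 3 voxels).
#' @param r_threshold correlation cutoff in (-1, 1); default 0.25.
#' @param weighted sum supra-threshold correlations (`TRUE`, default) or
#'   count them (`FALSE`).
#' @param block_size columns per correlation block (memory bound).
#' @return `measure_map` array, z-scored over the mask.
#' @export
degree_centrality_map <- function(bold, mask, r_threshold = 0.25,
                                  weighted = TRUE, block_size = 2048L) {
  stopifnot(r_threshold > -1, r_threshold < 1)
  vox <- which(mask$data)
  if (length(vox) < 3) stop("need at least 3 in-mask voxels")
  Y <- bold_matrix(bold, mask)
  n_time <- nrow(Y)
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  nrm <- sqrt(colSums(Yc^2))
  const <- nrm == 0
  if (any(const))
    warning(sum(const), " constant voxel series; correlations set to 0")
  nrm[const] <- 1
  Z <- sweep(Yc, 2, nrm, "/")           # unit-norm columns -> crossprod = r
  Z[, const] <- 0
  V <- ncol(Z)
  dc <- numeric(V)
  for (start in seq(1, V, by = block_size)) {
    cols <- start:min(start + block_size - 1L, V)
    R <- crossprod(Z[, cols, drop = FALSE], Z)     # block x V
    R[cbind(seq_along(cols), cols)] <- 0           # drop self-correlation
    Rt <- R > r_threshold
    dc[cols] <- if (weighted) rowSums(R * Rt) else rowSums(Rt)
  }
  s <- sd(dc)
  z <- if (s == 0) dc * 0 else (dc - mean(dc)) / s
  dims <- dim(bold$data)[1:3]
  out <- array(0, dim = dims); out[vox] <- z
  measure_map(out, "DC", bold$subject_id)
}

#' Seed-based functional connectivity map (Fisher z)
#'
#' The seed's mean series (average over seed voxels) is correlated with
#' every in-mask voxel series; correlations are clipped to
#' +/-(1 - 1e-7) and Fisher r-to-z transformed (`z = atanh(r)`).
#'
#' @param bold preprocessed [bold4d()].
#' @param mask the brain [mask_volume()].
#' @param seed a resolved seed [mask_volume()], subset of `mask`.
#' @param name measure label, default `"seedFC"`.
#' @return `measure_map` array of Fisher z values.
#' @export
seed_fc_map <- function(bold, mask, seed, name = "seedFC") {
  stopifnot(inherits(seed, "mask_volume"))
  if (!all(dim(seed$data) == dim(mask$data)))
    stop("seed dims do not match mask")
  if (any(seed$data & !mask$data))
    stop("seed has voxels outside the brain mask")
  seed_idx <- which(seed$data[mask$data])
  if (!length(seed_idx)) stop("empty seed")
  Y <- bold_matrix(bold, mask)
  seed_series <- rowMeans(Y[, seed_idx, drop = FALSE])
  if (sd(seed_series) == 0) stop("seed mean series is constant")
  r <- suppressWarnings(as.vector(cor(seed_series, Y)))
  r[!is.finite(r)] <- 0                  # constant voxel series
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  dims <- dim(bold$data)[1:3]
  out <- array(0, dim = dims); out[which(mask$data)] <- atanh(r)
  measure_map(out, name, bold$subject_id)
}

#' Canonical measure ordering for concatenation
#'
#' ReHo, fALFF, ALFF, DC first, then seed-based connectivity measures in
#' the order the seeds were supplied.
#' @param names character measure names present.
#' @return Reordered character vector.
#' @export
measure_order <- function(names) {
  fixed <- c("ReHo", "fALFF", "ALFF", "DC")
  c(intersect(fixed, names), setdiff(names, fixed))
}

#' Concatenate measure maps into a subjects x features matrix
#'
#' Columns are ordered by measure ([measure_order()]) and, within each
#' measure, by 1-based voxel linear index; rows follow the subject order of
#' `maps`. Per-measure selection masks restrict which voxels enter.
#'
#' @param maps list over subjects; each element a named list of
#'   `measure_map` arrays sharing dims.
#' @param mask a single [mask_volume()] applied to every measure, or a
#'   named list of logical arrays (one per measure, e.g. the output of
#'   [univariate_mask()]).
#' @param labels integer group labels (0/1), one per subject.
#' @return An object of class `feature_matrix`: list with `values`
#'   (n x q matrix), `labels`, and `columns` (tibble of measure + voxel
#'   provenance).
#' @export
build_feature_matrix <- function(maps, mask, labels) {
  stopifnot(length(maps) >= 1, length(labels) == length(maps))
  measures <- measure_order(names(maps[[1]]))
  for (s in seq_along(maps))
    if (!setequal(names(maps[[s]]), measures))
      stop("subject ", s, " is missing measures: ",
           paste(setdiff(measures, names(maps[[s]])), collapse = ", "))
  masks <- if (inherits(mask, "mask_volume")) {
    stats::setNames(rep(list(mask$data), length(measures)), measures)
  } else {
    if (!all(measures %in% names(mask)))
      stop("selection mask list is missing measures: ",
           paste(setdiff(measures, names(mask)), collapse = ", "))
    lapply(mask[measures], function(m)
      if (inherits(m, "mask_volume")) m$data else m)
  }
  cols <- dplyr::bind_rows(lapply(measures, function(m)
    tibble::tibble(measure = m, voxel = which(masks[[m]]))))
  values <- matrix(NA_real_, nrow = length(maps), ncol = nrow(cols))
  for (s in seq_along(maps)) {
    values[s, ] <- unlist(lapply(measures, function(m)
      as.numeric(maps[[s]][[m]])[masks[[m]]]), use.names = FALSE)
  }
  if (anyNA(values)) stop("missing values in feature matrix")
  rownames(values) <- names(maps) %||% paste0("sub", seq_along(maps))
  structure(list(values = values, labels = as.integer(labels),
                 columns = cols), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$columns$measure), collapse = ", ")))
  invisible(x)
}

#' Compute all measure maps for one subject
#'
#' Runs the standard chain: detrend (+ optional confound regression),
#' band-pass for ReHo/DC/seed-FC, full-spectrum ALFF/fALFF, then optional
#' map smoothing and per-subject z-scoring over the mask. Measures are
#' computed on unsmoothed series; smoothing is applied to the finished
#' measure maps.
#'
#' @param bold raw [bold4d()].
#' @param mask the brain [mask_volume()].
#' @param seeds named list of resolved seed masks ([mask_volume()]); each
#'   yields a `<name>-rsFC` measure.
#' @param config a [run_config()].
#' @param confounds optional nuisance matrix.
#' @return Named list of `measure_map` arrays.
#' @export
subject_measures <- function(bold, mask, seeds = list(),
                             config = run_config(), confounds = NULL) {
  pp <- preprocess_bold(bold, mask, band_hz = config$band_hz,
                        confounds = confounds,
                        drop_initial = config$drop_initial)
  af <- alff_falff_map(pp$unfiltered, mask, band_hz = config$band_hz)
  out <- list(
    ReHo = reho_map(pp$filtered, mask),
    fALFF = af$falff,
    ALFF = af$alff,
    DC = degree_centrality_map(pp$filtered, mask,
                               r_threshold = config$dc_r_threshold))
  for (nm in names(seeds))
    out[[paste0(nm, "-rsFC")]] <-
      seed_fc_map(pp$filtered, mask, seeds[[nm]], paste0(nm, "-rsFC"))
  if (config$fwhm_mm > 0)
    out <- lapply(out, function(m)
      measure_map(smooth_gaussian(unclass(m), config$fwhm_mm,
                                  bold$voxel_size_mm, mask),
                  attr(m, "measure"), bold$subject_id))
  if (isTRUE(config$scale_maps))
    out <- lapply(out, function(m) {
      v <- m[mask$data]
      s <- sd(v)
      z <- unclass(m)
      z[mask$data] <- if (s == 0) 0 else (v - mean(v)) / s
      measure_map(z, attr(m, "measure"), attr(m, "subject_id"))
    })
  out
}
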
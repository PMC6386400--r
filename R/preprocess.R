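# Temporal cleanup of already-aligned BOLD runs: linear detrending, ideal
# FFT band-pass, nuisance regression, and separable Gaussian smoothing.
# All operations act on in-mask voxels and zero everything outside.

# T x V matrix of the in-mask voxel series (columns in mask linear order)
bold_matrix <- function(bold, mask) {
  dims <- dim(bold$data)
  if (!all(dim(mask$data) == dims[1:3]))
    stop("mask dims do not match BOLD spatial dims")
  vox <- which(mask$data)
  m <- matrix(bold$data, nrow = prod(dims[1:3]), ncol = dims[4])
  t(m[vox, , drop = FALSE])
}

# inverse of bold_matrix: put T x V back into a bold4d, zero outside mask
matrix_to_bold <- function(Y, bold, mask) {
  dims <- dim(bold$data)
  vox <- which(mask$data)
  m <- matrix(0, nrow = prod(dims[1:3]), ncol = dims[4])
  m[vox, ] <- t(Y)
  out <- bold
  out$data <- array(m, dim = dims)
  out
}

#' Remove the per-voxel linear trend
#'
#' Least-squares line (intercept + slope over scan time) removed from every
#' in-mask voxel series; out-of-mask voxels are zeroed.
#'
#' @param bold a [bold4d()] with T >= 3.
#' @param mask the brain [mask_volume()].
#' @return A detrended [bold4d()].
#' @export
detrend_linear <- function(bold, mask) {
  stopifnot(inherits(bold, "bold4d"), dim(bold$data)[4] >= 3)
  Y <- bold_matrix(bold, mask)
  X <- cbind(1, seq_len(nrow(Y)))
  beta <- qr.solve(X, Y)
  matrix_to_bold(Y - X %*% beta, bold, mask)
}

#' Ideal frequency-domain band-pass filter
#'
#' FFT bins with |f| outside `[low, high]` are zeroed and the series
#' inverse-transformed; the DC bin is always removed, so output series have
#' exactly zero temporal mean.
#'
#' @param bold a [bold4d()].
#' @param band_hz length-2 band (low, high), 0 < low < high <= Nyquist.
#' @param mask the brain [mask_volume()].
#' @return A filtered [bold4d()].
#' @export
bandpass <- function(bold, band_hz, mask) {
  stopifnot(inherits(bold, "bold4d"), length(band_hz) == 2L,
            band_hz[1] > 0, band_hz[2] > band_hz[1])
  n_time <- dim(bold$data)[4]
  nyq <- 1 / (2 * bold$tr_s)
  if (band_hz[1] >= nyq) stop("empty passband: low edge at or above Nyquist")
  freqs <- (seq_len(n_time) - 1) / (n_time * bold$tr_s)
  freqs <- pmin(freqs, 1 / bold$tr_s - freqs)        # |f| of each bin
  keep <- freqs >= band_hz[1] & freqs <= band_hz[2]
  if (!any(keep))
    stop("empty passband: no FFT bins between ", band_hz[1], " and ",
         band_hz[2], " Hz at T = ", n_time)
  Y <- bold_matrix(bold, mask)
  sp <- mvfft(Y)
  sp[!keep, ] <- 0
  matrix_to_bold(Re(mvfft(sp, inverse = TRUE)) / n_time, bold, mask)
}

#' Regress nuisance signals out of every voxel series
#'
#' Each in-mask voxel series is replaced by the residual of an ordinary
#' least-squares fit on an intercept plus the confound columns (e.g. CSF
#' mean, white-matter mean, motion parameters supplied by the user).
#'
#' @param bold a [bold4d()].
#' @param confounds T x C numeric matrix or data frame of regressors (may
#'   have zero columns, in which case only the mean is removed).
#' @param mask the brain [mask_volume()].
#' @return A residualised [bold4d()].
#' @export
regress_confounds <- function(bold, confounds, mask) {
  stopifnot(inherits(bold, "bold4d"))
  n_time <- dim(bold$data)[4]
  C <- as.matrix(confounds)
  if (length(C) && nrow(C) != n_time)
    stop("confound rows (", nrow(C), ") do not match volume count (",
         n_time, ")")
  if (length(C) && !all(is.finite(C))) stop("non-finite confound values")
  X <- cbind(intercept = rep(1, n_time), C)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient confound design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  Y <- bold_matrix(bold, mask)
  matrix_to_bold(Y - X %*% qr.coef(qrx, Y), bold, mask)
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = dim(arr))
  n <- dim(arr)[axis]
  for (o in -r:r) {
    src <- seq_len(n) + o          # zero-padded shift along the axis
    ok <- src >= 1 & src <= n
    if (!any(ok)) next
    idx_dst <- idx_src <- rep(list(quote(expr = )), length(dim(arr)))
    idx_dst[[axis]] <- which(ok)
    idx_src[[axis]] <- src[ok]
    dst <- do.call(`[`, c(list(arr), idx_src, list(drop = FALSE)))
    ref <- do.call(`[`, c(list(out), idx_dst, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), idx_dst,
                            list(ref + kernel[o + r + 1L] * dst)))
  }
  out
}

#' Separable 3-D Gaussian smoothing
#'
#' Per-axis sigma is `fwhm / (voxel_size * 2 * sqrt(2 * log(2)))` voxels.
#' Convolution is zero-padded; with `mask` given, the result is restricted
#' to the mask afterwards (values near mask edges are attenuated by the
#' zero padding — see the methods vignette). `fwhm_mm = 0` is the identity.
#'
#' @param x 3-D array, [mask_volume()]-shaped map, or [bold4d()] (smoothed
#'   volume by volume).
#' @param fwhm_mm full width at half maximum in mm (>= 0).
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param mask optional [mask_volume()]; output zeroed outside it.
#' @return Same shape as `x`.
#' @export
smooth_gaussian <- function(x, fwhm_mm, voxel_size_mm, mask = NULL) {
  stopifnot(fwhm_mm >= 0)
  voxel_size_mm <- rep_len(voxel_size_mm, 3L)
  if (inherits(x, "bold4d")) {
    out <- x
    for (t in seq_len(dim(x$data)[4]))
      out$data[, , , t] <- smooth_gaussian(x$data[, , , t], fwhm_mm,
                                           voxel_size_mm, mask)
    return(out)
  }
  if (fwhm_mm == 0) {
    out <- x
  } else {
    out <- x
    for (axis in 1:3) {
      sigma <- fwhm_to_sigma_vox(fwhm_mm, voxel_size_mm[axis])
      out <- convolve_axis(out, gaussian_kernel_1d(sigma), axis)
    }
  }
  if (!is.null(mask)) out[!mask$data] <- 0
  out
}

#' Standard temporal preprocessing chain
#'
#' Applies, in order: initial-volume discard, linear detrending, ideal
#' band-pass filtering, and nuisance regression. ALFF/fALFF need the full
#' spectrum, so the function also returns the unfiltered (detrended and
#' residualised, but not band-passed) run.
#'
#' @param bold a [bold4d()].
#' @param mask the brain [mask_volume()].
#' @param band_hz pass band in Hz.
#' @param confounds optional T x C regressor matrix (rows after discard).
#' @param drop_initial number of initial volumes discarded before anything
#'   else.
#' @return List with `filtered` (band-passed [bold4d()]) and `unfiltered`
#'   (detrended/residualised only) elements.
#' @export
preprocess_bold <- function(bold, mask, band_hz = c(0.01, 0.08),
                            confounds = NULL, drop_initial = 0L) {
  stopifnot(inherits(bold, "bold4d"))
  if (drop_initial > 0) {
    if (dim(bold$data)[4] - drop_initial < 3)
      stop("too few volumes left after dropping ", drop_initial)
    bold$data <- bold$data[, , , -seq_len(drop_initial), drop = FALSE]
  }
  b <- detrend_linear(bold, mask)
  filtered <- bandpass(b, band_hz, mask)
  if (!is.null(confounds) && length(as.matrix(confounds))) {
    filtered <- regress_confounds(filtered, confounds, mask)
    b <- regress_confounds(b, confounds, mask)
  }
  list(filtered = filtered, unfiltered = b)
}
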
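#' Band-limited unit-variance latent series
#'
#' Constructs a random series directly in the frequency domain: complex
#' Gaussian coefficients are placed on the FFT bins whose frequency falls in
#' `band_hz`, all other bins are zero, and the inverse transform is scaled
#' to exactly unit sample variance. By construction the spectral mass
#' outside the band is zero and the temporal mean is zero.
#'
#' @param band_hz length-2 band (low, high) in Hz; must contain at least one
#'   positive FFT bin at the given `n_time`/`tr_s`.
#' @param n_time number of time points.
#' @param tr_s repetition time in seconds.
#' @return Numeric vector of length `n_time` with mean 0 and variance 1.
#' @export
make_latent <- function(band_hz, n_time, tr_s) {
  stopifnot(length(band_hz) == 2L, band_hz[1] >= 0, band_hz[2] > band_hz[1],
            n_time >= 4, tr_s > 0)
  nyq <- 1 / (2 * tr_s)
  if (band_hz[1] > nyq) stop("band starts above the Nyquist frequency ",
                             signif(nyq, 4), " Hz")
  freqs <- (seq_len(n_time) - 1) / (n_time * tr_s)      # bin frequencies
  half <- 2:(floor(n_time / 2) + 1)                     # positive bins
  in_band <- half[freqs[half] >= band_hz[1] & freqs[half] <= band_hz[2]]
  if (!length(in_band))
    stop("no FFT bins fall inside the band at T = ", n_time,
         ", TR = ", tr_s, " s; lengthen the series or widen the band")
  spec <- complex(length.out = n_time)
  coef <- complex(real = rnorm(length(in_band)),
                  imaginary = rnorm(length(in_band)))
  spec[in_band] <- coef
  # conjugate symmetry for a real-valued series; Nyquist bin kept real
  conj_idx <- n_time - in_band + 2L
  keep <- conj_idx <= n_time & conj_idx != in_band
  spec[conj_idx[keep]] <- Conj(coef[keep])
  if (any(!keep)) spec[in_band[!keep]] <- complex(real = Re(coef[!keep]))
  x <- Re(fft(spec, inverse = TRUE)) / n_time
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) stop("degenerate latent series (zero variance)")
  x / s
}

#' Define a planted group effect for the synthetic cohort
#'
#' Three effect kinds emulate the signal families the measures target:
#' `"coherence"` adds one shared band-limited latent to every voxel of its
#' region (raising within-region Kendall-W concordance and band power);
#' `"amplitude"` adds an independent band-limited latent per voxel (raising
#' ALFF/fALFF without inter-voxel coherence); `"coupling"` adds the same
#' latent to the region and a partner region (raising seed-based
#' connectivity and degree centrality). The group difference is encoded
#' purely in the amplitude pair.
#'
#' @param kind `"coherence"`, `"amplitude"` or `"coupling"`.
#' @param region a [seed_spec()] for the affected region.
#' @param group_amplitudes length-2 non-negative amplitudes
#'   (group 0, group 1) in units of the noise SD.
#' @param band_hz band of the latent series.
#' @param partner_region partner [seed_spec()] (coupling only).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(kind = c("coherence", "amplitude", "coupling"),
                        region, group_amplitudes,
                        band_hz = c(0.01, 0.08), partner_region = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(region, "seed_spec"),
            length(group_amplitudes) == 2L, all(group_amplitudes >= 0))
  if (kind == "coupling" && is.null(partner_region))
    stop("coupling effects need a partner_region")
  structure(list(kind = kind, region = region,
                 group_amplitudes = as.numeric(group_amplitudes),
                 band_hz = band_hz, partner_region = partner_region),
            class = "effect_spec")
}

#' Define a two-group synthetic BOLD cohort
#'
#' Voxel noise is a stationary Gaussian AR(1) process (marginal SD
#' `noise_sd`, lag-1 coefficient `noise_ar1_phi`); group effects from
#' `effects` are added on top. The default geometry (24^3 grid, 120 volumes,
#' TR 3 s, 20 + 20 subjects) keeps a full pipeline run desk-scale.
#'
#' @param n_per_group length-2 integer (n group 0, n group 1), each >= 2.
#' @param dims length-3 spatial grid.
#' @param n_volumes number of time points (>= 32).
#' @param tr_s repetition time in seconds.
#' @param voxel_size_mm voxel size (isotropic default 3 mm).
#' @param noise_ar1_phi AR(1) coefficient, |phi| < 1.
#' @param noise_sd marginal noise SD.
#' @param effects list of [effect_spec()] objects.
#' @param mask optional brain [mask_volume()]; default is an inscribed
#'   ellipsoid two voxels short of the grid faces.
#' @param rng_seed master seed for the generator.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(20L, 20L), dims = c(24L, 24L, 24L),
                        n_volumes = 120L, tr_s = 3, voxel_size_mm = 3,
                        noise_ar1_phi = 0.3, noise_sd = 1,
                        effects = list(), mask = NULL, rng_seed = 1L) {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 2),
            length(dims) == 3L, all(dims >= 4), n_volumes >= 32,
            tr_s > 0, abs(noise_ar1_phi) < 1, noise_sd > 0)
  voxel_size_mm <- rep_len(voxel_size_mm, 3L)
  affine <- diag(c(voxel_size_mm, 1))
  if (is.null(mask)) {
    g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                     k = seq_len(dims[3]))
    c0 <- (dims + 1) / 2
    r <- pmax(dims / 2 - 2, 1)
    inside <- ((g$i - c0[1]) / r[1])^2 + ((g$j - c0[2]) / r[2])^2 +
      ((g$k - c0[3]) / r[3])^2 <= 1
    mask <- mask_volume(array(inside, dim = dims), affine = affine)
  }
  structure(list(n_per_group = as.integer(n_per_group), dims = as.integer(dims),
                 n_volumes = as.integer(n_volumes), tr_s = tr_s,
                 voxel_size_mm = voxel_size_mm, affine = affine,
                 noise_ar1_phi = noise_ar1_phi, noise_sd = noise_sd,
                 effects = effects, mask = mask,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

resolve_effects <- function(spec) {
  lapply(spec$effects, function(e) {
    region <- resolve_seed(e$region, spec$mask)
    partner <- if (!is.null(e$partner_region))
      resolve_seed(e$partner_region, spec$mask) else NULL
    list(kind = e$kind, region_vox = which(region$data),
         partner_vox = if (!is.null(partner)) which(partner$data),
         group_amplitudes = e$group_amplitudes, band_hz = e$band_hz,
         name = e$region$name)
  })
}

check_effect_overlap <- function(resolved) {
  n <- length(resolved)
  if (n < 2) return(invisible())
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (resolved[[a]]$kind == resolved[[b]]$kind) next
    ov <- intersect(resolved[[a]]$region_vox, resolved[[b]]$region_vox)
    if (length(ov))
      stop("effects ", a, " (", resolved[[a]]$kind, ") and ", b, " (",
           resolved[[b]]$kind, ") overlap with contradictory kinds at ",
           "voxel indices: ", paste(head(ov, 20), collapse = ", "),
           if (length(ov) > 20) " ..." else "")
  }
  invisible()
}

# stationary AR(1) noise, T x V, marginal SD sd
ar1_noise <- function(n_time, n_vox, phi, sd) {
  x <- matrix(0, n_time, n_vox)
  x[1, ] <- rnorm(n_vox, sd = sd)
  innov_sd <- sd * sqrt(1 - phi^2)
  for (t in 2:n_time) x[t, ] <- phi * x[t - 1, ] + rnorm(n_vox, sd = innov_sd)
  x
}

#' Generate a synthetic two-group BOLD cohort
#'
#' Writes one NIfTI per subject, the brain mask, a manifest CSV
#' (`subject_id,label,path`) and a JSON sidecar recording the resolved
#' ground-truth voxel sets of every planted effect (for recovery scoring).
#' Bitwise reproducible from `spec$rng_seed`.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if missing).
#' @return A tibble manifest with columns `subject_id`, `label`, `path`, and
#'   attributes `mask_path` and `truth_path`.
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  resolved <- resolve_effects(spec)
  check_effect_overlap(resolved)

  dims <- spec$dims
  n_vox <- prod(dims)
  n_time <- spec$n_volumes
  labels <- rep(c(0L, 1L), spec$n_per_group)
  ids <- sprintf("sub-%03d", seq_along(labels))
  paths <- file.path(out_dir, paste0(ids, ".nii.gz"))

  for (s in seq_along(labels)) {
    with_seed(substream_seed(spec$rng_seed, "cohort_subject", s), {
      sig <- matrix(0, n_time, n_vox)
      for (e in resolved) {
        amp <- e$group_amplitudes[labels[s] + 1L]
        if (e$kind == "amplitude") {
          for (v in e$region_vox)
            sig[, v] <- sig[, v] +
              amp * make_latent(e$band_hz, n_time, spec$tr_s)
        } else {
          lat <- make_latent(e$band_hz, n_time, spec$tr_s)
          vox <- c(e$region_vox, e$partner_vox)
          sig[, vox] <- sig[, vox] + amp * lat
        }
      }
      noise <- ar1_noise(n_time, n_vox, spec$noise_ar1_phi, spec$noise_sd)
      arr <- array(t(sig + noise), dim = c(dims, n_time))
      b <- bold4d(arr, voxel_size_mm = spec$voxel_size_mm, tr_s = spec$tr_s,
                  affine = spec$affine, subject_id = ids[s])
      write_bold4d(b, paths[s])
    })
  }

  mask_path <- file.path(out_dir, "mask.nii.gz")
  write_mask(spec$mask, mask_path, voxel_size_mm = spec$voxel_size_mm)

  truth <- list(
    dims = dims, tr_s = spec$tr_s, noise_ar1_phi = spec$noise_ar1_phi,
    noise_sd = spec$noise_sd, rng_seed = spec$rng_seed,
    effects = lapply(resolved, function(e)
      list(kind = e$kind, name = e$name,
           group_amplitudes = e$group_amplitudes,
           region_vox = e$region_vox, partner_vox = e$partner_vox)))
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)

  manifest <- tibble::tibble(subject_id = ids, label = labels, path = paths)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "mask_path") <- mask_path
  attr(manifest, "truth_path") <- truth_path
  manifest
}

#' Demonstration cohort: the package's reference study conditions
#'
#' A two-group cohort of 20 + 20 subjects on a 24^3 grid of 3-mm voxels,
#' 120 volumes at TR = 3 s, AR(1) noise (phi 0.3, SD 1), with three strong
#' planted effects: a coherence region, an amplitude region, and a coupled
#' region pair, all spheres of 2.5-voxel radius in distinct octants.
#' Group-0/group-1 amplitudes are (0.5, 2) for coherence and amplitude and
#' (0.375, 1.5) for coupling, i.e. clear but not degenerate group
#' separation. These are the conditions exercised by the test suite and
#' the acceptance script.
#'
#' @param rng_seed master generator seed.
#' @param n_per_group,dims,n_volumes overrides for scaled-down runs.
#' @return A [cohort_spec()].
#' @export
demo_cohort_spec <- function(rng_seed = 42L, n_per_group = c(20L, 20L),
                             dims = c(24L, 24L, 24L), n_volumes = 120L) {
  s <- demo_region_seeds(dims)
  effects <- list(
    effect_spec("coherence", s$coh, c(0.5, 2.0)),
    effect_spec("amplitude", s$amp, c(0.5, 2.0)),
    effect_spec("coupling", s$cplA, c(0.375, 1.5), partner_region = s$cplB))
  cohort_spec(n_per_group = n_per_group, dims = dims, n_volumes = n_volumes,
              tr_s = 3, voxel_size_mm = 3, noise_ar1_phi = 0.3,
              noise_sd = 1, effects = effects, rng_seed = rng_seed)
}

#' Planted-region seed definitions used by [demo_cohort_spec()]
#' @param dims grid dimensions the regions are placed in.
#' @return Named list of [seed_spec()] objects (coh, amp, cplA, cplB).
#' @export
demo_region_seeds <- function(dims = c(24L, 24L, 24L)) {
  lo <- round(dims / 3); hi <- round(2 * dims / 3); mid <- round(dims / 2)
  r <- min(dims) * 2.5 / 24              # 2.5 voxels at the 24^3 reference,
                                         # shrunk proportionally so regions
                                         # never collide on smaller grids
  list(coh = seed_spec("coh", center_vox = c(lo[1], lo[2], mid[3]),
                       radius_vox = r),
       amp = seed_spec("amp", center_vox = c(hi[1], hi[2], mid[3]),
                       radius_vox = r),
       cplA = seed_spec("cplA", center_vox = c(lo[1], hi[2], mid[3]),
                        radius_vox = r),
       cplB = seed_spec("cplB", center_vox = c(hi[1], lo[2], mid[3]),
                        radius_vox = r))
}

#' Ground-truth planted voxel set of a generated cohort
#' @param truth_path path to the `ground_truth.json` sidecar.
#' @return Sorted integer vector of 1-based voxel linear indices.
#' @export
planted_voxels <- function(truth_path) {
  truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  sort(unique(unlist(c(truth$effects$region_vox,
                       truth$effects$partner_vox))))
}
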
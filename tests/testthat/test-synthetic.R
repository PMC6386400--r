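test_that("latent series are unit-variance and band-limited", {
  set.seed(1)
  for (i in 1:5) {
    x <- make_latent(c(0.01, 0.08), 120, 3)
    expect_equal(var(x), 1, tolerance = 1e-9)
    expect_lt(abs(mean(x)), 1e-12)
    # periodogram integration: >= 99% of power inside the band
    p <- Mod(fft(x))^2
    fr <- (0:119) / (120 * 3)
    half <- 2:61
    in_band <- fr[half] >= 0.01 & fr[half] <= 0.08
    expect_gte(sum(p[half][in_band]) / sum(p[half]), 0.99)
  }
})

test_that("latent generation errors when no FFT bin falls in the band", {
  # T = 32, TR = 0.5 s: fundamental 1/16 Hz = 0.0625 > 0.05
  expect_error(make_latent(c(0.001, 0.002), 32, 0.5), "no FFT bins")
  expect_error(make_latent(c(2, 3), 64, 3), "Nyquist")
})

test_that("null cohorts have near-zero within-region correlation", {
  coh <- null_cohort()
  b <- read_bold4d(coh$manifest$path[1])
  region <- resolve_seed(seed_spec("r", center_vox = c(7, 7, 7),
                                   radius_vox = 2), coh$mask)
  idx <- which(region$data)
  Y <- t(matrix(b$data, ncol = dim(b$data)[4])[idx, ])
  C <- cor(Y)
  mean_r <- mean(C[upper.tri(C)])
  expect_lt(abs(mean_r), 0.08)     # ~30 voxels, T = 64, null
})

test_that("a strong coherence effect yields high within-region correlation", {
  # signal sd = 3 x noise sd => expected pairwise r = 9/10
  dir <- withr::local_tempdir()
  region <- seed_spec("r", center_vox = c(5, 5, 5), radius_vox = 1.5)
  spec <- cohort_spec(n_per_group = c(2, 2), dims = c(10, 10, 10),
                      n_volumes = 120, tr_s = 3,
                      effects = list(effect_spec("coherence", region,
                                                 c(3, 3))),
                      rng_seed = 9)
  man <- generate_cohort(spec, dir)
  mask <- read_mask(attr(man, "mask_path"))
  idx <- which(resolve_seed(region, mask)$data)
  b <- read_bold4d(man$path[1])
  Y <- t(matrix(b$data, ncol = 120)[idx, ])
  C <- cor(Y)
  expect_gt(mean(C[upper.tri(C)]), 0.5)
})

test_that("cohort generation is bitwise deterministic under a fixed seed", {
  spec <- cohort_spec(n_per_group = c(2, 2), dims = c(8, 8, 8),
                      n_volumes = 40, tr_s = 3,
                      effects = demo_effects()[1], rng_seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_cohort(spec, d1)
  m2 <- generate_cohort(spec, d2)
  for (i in seq_len(nrow(m1))) {
    expect_identical(unname(tools::md5sum(m1$path[i])),
                     unname(tools::md5sum(m2$path[i])))
  }
})

test_that("overlapping effects of contradictory kinds are rejected", {
  r1 <- seed_spec("a", center_vox = c(5, 5, 5), radius_vox = 2)
  r2 <- seed_spec("b", center_vox = c(6, 5, 5), radius_vox = 2)
  spec <- cohort_spec(n_per_group = c(2, 2), dims = c(10, 10, 10),
                      n_volumes = 40,
                      effects = list(effect_spec("coherence", r1, c(1, 1)),
                                     effect_spec("amplitude", r2, c(1, 1))),
                      rng_seed = 1)
  expect_error(generate_cohort(spec, withr::local_tempdir()),
               "contradictory kinds")
})

test_that("null-cohort voxelwise t retains about 5% at alpha 0.05", {
  coh <- null_cohort()
  cfg <- run_config(fwhm_mm = 0, scale_maps = FALSE, alpha_voxel = 0.05,
                    min_cluster_voxels = 1)
  maps <- cohort_measure_maps(coh, cfg)
  lab <- coh$manifest$label
  measures <- names(maps[[1]])
  rates <- vapply(measures, function(m) {
    tm <- two_sample_t_map(lapply(which(lab == 0), function(s) maps[[s]][[m]]),
                           lapply(which(lab == 1), function(s) maps[[s]][[m]]),
                           coh$mask)
    supra <- abs(tm$t) >= critical_t(0.05, tm$df) & coh$mask$data
    sum(supra) / sum(coh$mask$data)
  }, numeric(1))
  # pooled over measures; ReHo/DC maps are spatially dependent, so the
  # band is wider than a strict independent-voxel binomial CI
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.09)
})

test_that("group-mean ReHo rises monotonically with coherence amplitude", {
  region <- seed_spec("r", center_vox = c(5, 5, 5), radius_vox = 1.5)
  reho_at_amp <- function(a) {
    dir <- withr::local_tempdir()
    spec <- cohort_spec(n_per_group = c(2, 2), dims = c(10, 10, 10),
                        n_volumes = 64,
                        effects = list(effect_spec("coherence", region,
                                                   c(a, a))),
                        rng_seed = 55)
    man <- generate_cohort(spec, dir)
    mask <- read_mask(attr(man, "mask_path"))
    idx <- resolve_seed(region, mask)$data
    mean(vapply(man$path, function(p) {
      b <- read_bold4d(p)
      pp <- preprocess_bold(b, mask)
      mean(reho_map(pp$filtered, mask)[idx])
    }, numeric(1)))
  }
  vals <- vapply(c(0, 1, 3), reho_at_amp, numeric(1))
  expect_true(all(diff(vals) > 0))
})
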
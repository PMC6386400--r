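test_that("Kendall's W hits its boundary cases", {
  # identical strictly monotone series -> perfect concordance
  b <- matrix(rep(seq_len(10)^1.3, 4), nrow = 4, byrow = TRUE)
  expect_equal(kcc(b), 1)
  # two exactly reversed orderings -> all rank sums equal -> W = 0
  expect_equal(kcc(rbind(1:10, 10:1)), 0)
  expect_error(kcc(matrix(1, 1, 10)), "K = 2")
  expect_error(kcc(matrix(1, 3, 1)), "T = 2")
})

test_that("kcc matches the independent rank-definition oracle", {
  set.seed(21)
  for (i in 1:30) {
    K <- sample(2:8, 1); Tn <- sample(5:20, 1)
    block <- matrix(rnorm(K * Tn), K, Tn)
    expect_equal(kcc(block), kcc_oracle(block), tolerance = 1e-12)
    # invariance to monotone transforms of each series
    expect_equal(kcc(exp(block)), kcc(block), tolerance = 1e-12)
  }
})

test_that("ReHo map is 1 for a shared series and matches direct kcc", {
  dims <- c(5, 5, 5); n_time <- 20
  m <- full_mask(dims)
  tt <- seq_len(n_time)
  common <- sin(tt / 3) + 0.01 * tt
  b <- bold4d(array(rep(common, each = prod(dims)), c(dims, n_time)),
              rep(3, 3), 3)
  expect_true(all(abs(reho_map(b, m) - 1) < 1e-12))
  # interior voxel equals kcc() of the explicitly gathered 27 series
  br <- random_bold(dims, n_time, seed = 22)
  r <- reho_map(br, m, neighborhood = 27)
  block <- matrix(NA_real_, 27, n_time)
  i <- 0
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    i <- i + 1
    block[i, ] <- br$data[3 + dx, 3 + dy, 3 + dz, ]
  }
  expect_equal(r[3, 3, 3], kcc(block), tolerance = 1e-12)
  # 7- and 19-neighbourhoods accepted, others rejected
  expect_s3_class(reho_map(br, m, neighborhood = 7), "measure_map")
  expect_error(reho_map(br, m, neighborhood = 9), "neighborhood")
})

test_that("ReHo and fALFF stay in [0, 1] on random inputs", {
  set.seed(23)
  for (i in 1:5) {
    b <- random_bold(c(4, 4, 4), 30, seed = 23 + i)
    m <- full_mask(c(4, 4, 4))
    r <- reho_map(b, m)
    expect_true(all(r >= 0 & r <= 1))
    af <- alff_falff_map(b, m)
    expect_true(all(af$falff >= 0 & af$falff <= 1))
    expect_true(all(af$alff >= 0))
  }
})

test_that("fALFF is 1 for a pure in-band tone and 0 for silence", {
  dims <- c(2, 2, 2); n_time <- 120; tr <- 3
  m <- full_mask(dims)
  tt <- (seq_len(n_time) - 1) * tr
  s <- sin(2 * pi * (15 / 360) * tt)
  b <- bold4d(array(rep(s, each = prod(dims)), c(dims, n_time)), rep(3, 3), tr)
  af <- alff_falff_map(b, m)
  expect_equal(max(af$falff), 1, tolerance = 1e-9)
  expect_equal(min(af$falff), 1, tolerance = 1e-9)
  # zero series: ALFF 0, fALFF defined as 0 with a message
  b0 <- b; b0$data[] <- 0
  b0$data[1, 1, 1, ] <- s            # keep one live voxel
  expect_message(af0 <- alff_falff_map(b0, m), "zero spectrum")
  expect_equal(af0$alff[2, 2, 2], 0)
  expect_equal(af0$falff[2, 2, 2], 0)
  expect_equal(attr(af0$falff, "n_zero_spectrum"), 7)
})

test_that("white-noise fALFF approximates the band-bin fraction", {
  n_time <- 1024; tr <- 3
  dims <- c(4, 4, 4)
  b <- random_bold(dims, n_time, seed = 24, tr_s = tr)
  m <- full_mask(dims)
  af <- alff_falff_map(b, m, band_hz = c(0.01, 0.08))
  freqs <- (seq_len(n_time) - 1) / (n_time * tr)
  half <- 2:(n_time / 2 + 1)
  frac <- mean(freqs[half] >= 0.01 & freqs[half] <= 0.08)
  expect_equal(mean(af$falff), frac, tolerance = 0.02)
})

test_that("fALFF is invariant to global scaling", {
  b <- random_bold(c(3, 3, 3), 64, seed = 25)
  m <- full_mask(c(3, 3, 3))
  af1 <- alff_falff_map(b, m)
  b$data <- b$data * 7.5
  af2 <- alff_falff_map(b, m)
  expect_equal(unclass(af2$falff), unclass(af1$falff), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("degree centrality: hand case, z-scoring, and brute force", {
  # 3 voxels: v1 = v2, v3 = -v1 -> pre-z degrees (1, 1, 0) at r > 0.25
  set.seed(26)
  v <- rnorm(12)
  arr <- array(0, c(3, 1, 1, 12))
  arr[1, 1, 1, ] <- v; arr[2, 1, 1, ] <- v; arr[3, 1, 1, ] <- -v
  b <- bold4d(arr, rep(3, 3), 3)
  m <- full_mask(c(3, 1, 1))
  z <- degree_centrality_map(b, m)
  pre <- c(1, 1, 0)
  expect_equal(as.vector(unclass(z)), (pre - mean(pre)) / sd(pre),
               tolerance = 1e-9)
  # z-scored map: mask mean 0, SD 1 by construction
  b2 <- random_bold(c(4, 4, 3), 40, seed = 27)
  m2 <- full_mask(c(4, 4, 3))
  z2 <- degree_centrality_map(b2, m2)
  expect_lt(abs(mean(z2)), 1e-9)
  expect_equal(sd(as.vector(z2)), 1, tolerance = 1e-9)
  # brute-force O(V^2) oracle on a 48-voxel mask
  Y <- t(matrix(b2$data, ncol = 40)[seq_len(48), ])
  deg <- dc_oracle(Y, 0.25)
  expect_equal(as.vector(unclass(z2)), (deg - mean(deg)) / sd(deg),
               tolerance = 1e-9)
  # threshold -1, weighted: equals correlation row sums minus self
  zlow <- degree_centrality_map(b2, m2, r_threshold = -0.999999)
  C <- cor(Y)
  rs <- rowSums(C) - 1
  expect_equal(as.vector(unclass(zlow)), (rs - mean(rs)) / sd(rs),
               tolerance = 1e-6)
  # constant series warn and get zero correlations
  b2$data[1, 1, 1, ] <- 3
  expect_warning(degree_centrality_map(b2, m2), "constant")
})

test_that("seed FC applies Fisher z with clipping", {
  dims <- c(4, 4, 4); n_time <- 30
  b <- random_bold(dims, n_time, seed = 28)
  m <- full_mask(dims)
  sd_arr <- array(FALSE, dims); sd_arr[1, 1, 1] <- TRUE
  seedm <- mask_volume(sd_arr)
  z <- seed_fc_map(b, m, seedm)
  # a voxel identical to the seed mean hits the clip, stays finite
  expect_equal(z[1, 1, 1], atanh(1 - 1e-7))
  expect_true(all(is.finite(z)))
  # z matches atanh(r) for ordinary voxels
  r <- cor(b$data[1, 1, 1, ], b$data[2, 2, 2, ])
  expect_equal(z[2, 2, 2], atanh(r), tolerance = 1e-12)
  # atanh checks: r = 0 -> 0; r = 0.5 -> 0.5493; monotone in r
  expect_equal(atanh(0), 0)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  rr <- seq(-0.9, 0.9, by = 0.1)
  expect_true(all(diff(atanh(rr)) > 0))
  # z invariant to positive scaling of voxel series
  b3 <- b; b3$data <- b3$data * 4
  z3 <- seed_fc_map(b3, m, seedm)
  expect_equal(unclass(z3), unclass(z), tolerance = 1e-9,
               ignore_attr = TRUE)
  # seed outside the mask is rejected
  small <- array(TRUE, dims); small[1, 1, 1] <- FALSE
  expect_error(seed_fc_map(b, mask_volume(small), seedm), "outside")
})

test_that("feature matrix concatenation orders, counts and permutes", {
  dims <- c(3, 3, 2)
  m <- full_mask(dims)
  set.seed(29)
  mk <- function() {
    list(ReHo = boldmvpa:::measure_map(array(runif(prod(dims)), dims), "ReHo"),
         ALFF = boldmvpa:::measure_map(array(runif(prod(dims)), dims), "ALFF"))
  }
  maps <- list(s1 = mk(), s2 = mk())
  sel <- array(FALSE, dims); sel[1:5] <- TRUE     # 5 voxels per measure
  fm <- build_feature_matrix(maps, list(ReHo = sel, ALFF = sel), c(0, 1))
  expect_equal(dim(fm$values), c(2, 10))
  expect_equal(fm$columns$measure, rep(c("ReHo", "ALFF"), each = 5))
  expect_equal(fm$columns$voxel, rep(1:5, 2))
  # single measure: values equal the flattened masked map
  fm1 <- build_feature_matrix(lapply(maps, function(x) x["ReHo"]), m, c(0, 1))
  expect_equal(fm1$values[1, ], as.numeric(maps$s1$ReHo)[m$data])
  # shuffling subject order permutes rows only
  fm2 <- build_feature_matrix(maps[c("s2", "s1")],
                              list(ReHo = sel, ALFF = sel), c(1, 0))
  expect_equal(fm2$values[1, ], fm$values[2, ])
  expect_equal(fm2$columns, fm$columns)
  # missing measure errors
  bad <- maps; bad$s2$ALFF <- NULL
  expect_error(build_feature_matrix(bad, m, c(0, 1)), "missing measures")
})

test_that("measure ordering is ReHo, fALFF, ALFF, DC, then seeds", {
  expect_equal(measure_order(c("cplA-rsFC", "DC", "ALFF", "ReHo", "fALFF")),
               c("ReHo", "fALFF", "ALFF", "DC", "cplA-rsFC"))
})
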
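# Shared fixtures and independent oracles. Everything is generated in code;
# expensive cohorts are built once per session and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

random_bold <- function(dims = c(4, 4, 4), n_time = 40, seed = 1,
                        tr_s = 3, voxel_mm = 3) {
  set.seed(seed)
  bold4d(array(rnorm(prod(dims) * n_time), c(dims, n_time)),
         voxel_size_mm = rep(voxel_mm, 3), tr_s = tr_s)
}

full_mask <- function(dims = c(4, 4, 4), voxel_mm = 3) {
  mask_volume(array(TRUE, dims), affine = diag(c(rep(voxel_mm, 3), 1)))
}

# --- independent oracles -------------------------------------------------

# Kendall's W straight from its rank definition, coded independently of
# kcc(): rank each series, sum ranks per time point, variance ratio.
kcc_oracle <- function(block) {
  K <- nrow(block); Tn <- ncol(block)
  R <- numeric(Tn)
  for (i in seq_len(K)) R <- R + rank(block[i, ])
  S <- sum((R - mean(R))^2)
  12 * S / (K^2 * (Tn^3 - Tn))
}

# O(V^2) brute-force weighted degree centrality (pre z-scoring)
dc_oracle <- function(series_matrix, r_threshold) {
  V <- ncol(series_matrix)
  deg <- numeric(V)
  for (v in seq_len(V)) {
    for (u in seq_len(V)) {
      if (u == v) next
      r <- suppressWarnings(cor(series_matrix[, v], series_matrix[, u]))
      if (is.na(r)) r <- 0
      if (r > r_threshold) deg[v] <- deg[v] + r
    }
  }
  deg
}

# BFS flood-fill connected-component labelling
flood_fill_labels <- function(binary, connectivity = 26) {
  dims <- dim(binary)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  d <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  off <- switch(as.character(connectivity),
                "6" = off[d == 1, ], "18" = off[d <= 2, ], "26" = off)
  lab <- array(0L, dims)
  nxt <- 0L
  for (start in which(binary != 0)) {
    if (lab[start] > 0) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, dims)
      for (r in seq_len(nrow(off))) {
        nb <- co + c(off$dx[r], off$dy[r], off$dz[r])
        if (any(nb < 1) || any(nb > dims)) next
        lin <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
        if (binary[lin] != 0 && lab[lin] == 0) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# same partition regardless of label numbering?
same_partition <- function(a, b) {
  va <- a[a > 0]; vb <- b[b > 0]
  if (length(va) != length(vb)) return(FALSE)
  all(tapply(vb, va, function(x) length(unique(x))) == 1) &&
    all(tapply(va, vb, function(x) length(unique(x))) == 1)
}

# --- shared small cohorts ------------------------------------------------

demo_seeds <- function() {
  list(
    coh = seed_spec("coh", center_vox = c(5, 5, 8), radius_vox = 2),
    amp = seed_spec("amp", center_vox = c(11, 11, 8), radius_vox = 2),
    cplA = seed_spec("cplA", center_vox = c(5, 11, 8), radius_vox = 2),
    cplB = seed_spec("cplB", center_vox = c(11, 5, 8), radius_vox = 2))
}

demo_effects <- function(strength = c(0.5, 2.0)) {
  s <- demo_seeds()
  list(effect_spec("coherence", s$coh, strength),
       effect_spec("amplitude", s$amp, strength),
       effect_spec("coupling", s$cplA, strength * 0.75,
                   partner_region = s$cplB))
}

# small planted-effect cohort: 6+6 subjects, 16^3 x 64
effect_cohort <- function() {
  memoise_fixture("effect_cohort", function() {
    dir <- file.path(tempdir(), "boldmvpa-effect-cohort")
    spec <- cohort_spec(n_per_group = c(6, 6), dims = c(16, 16, 16),
                        n_volumes = 64, tr_s = 3,
                        effects = demo_effects(), rng_seed = 101)
    man <- generate_cohort(spec, dir)
    list(manifest = man, spec = spec,
         mask = read_mask(attr(man, "mask_path")),
         truth = jsonlite::read_json(attr(man, "truth_path"),
                                     simplifyVector = TRUE))
  })
}

# null cohort: no effects at all, 6+6 subjects
null_cohort <- function() {
  memoise_fixture("null_cohort", function() {
    dir <- file.path(tempdir(), "boldmvpa-null-cohort")
    spec <- cohort_spec(n_per_group = c(6, 6), dims = c(14, 14, 14),
                        n_volumes = 64, tr_s = 3, effects = list(),
                        rng_seed = 202)
    man <- generate_cohort(spec, dir)
    list(manifest = man, spec = spec,
         mask = read_mask(attr(man, "mask_path")))
  })
}

fast_config <- function(...) {
  defaults <- list(alpha_voxel = 0.001, min_cluster_voxels = 4,
                   selector = "ttest+rfe", classifier = "elm",
                   cv = list(kind = "kfold", k = 4),
                   elm = list(L_grid = c(10, 25, 50), n_repeats = 3,
                              inner_folds = 3),
                   k_grid = c(5, 10, 20, 40), n_permutations = 200,
                   rng_seed = 7)
  do.call(run_config, utils::modifyList(defaults, list(...)))
}

cohort_measure_maps <- function(cohort, config, seeds = NULL) {
  man <- cohort$manifest
  resolved <- lapply(seeds %||% list(),
                     function(s) resolve_seed(s, cohort$mask))
  maps <- lapply(seq_len(nrow(man)), function(i)
    subject_measures(read_bold4d(man$path[i]), cohort$mask,
                     seeds = resolved, config = config))
  names(maps) <- man$subject_id
  maps
}

# measure maps for the planted-effect cohort (memoised; used across files)
effect_cohort_maps <- function() {
  memoise_fixture("effect_cohort_maps", function() {
    cohort_measure_maps(effect_cohort(), fast_config(),
                        seeds = list(cplA = demo_seeds()$cplA))
  })
}
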
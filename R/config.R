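#' Build and validate a run configuration
#'
#' Central bundle of the tunable parameters of the analysis pipeline.
#' Defaults follow the analysis conventions of resting-state toolchains:
#' 0.01-0.08 Hz pass band, 6-mm FWHM smoothing of measure maps, voxelwise
#' two-tailed alpha of 0.05, degree-centrality threshold r > 0.25, and a
#' 1000-permutation significance test.
#'
#' @param band_hz length-2 pass band (low, high) in Hz.
#' @param fwhm_mm Gaussian smoothing FWHM in mm applied to measure maps
#'   (0 disables smoothing).
#' @param drop_initial number of initial volumes discarded at load.
#' @param alpha_voxel voxelwise two-tailed alpha for the univariate t mask.
#' @param alpha_cluster cluster-level alpha for the Monte-Carlo cluster
#'   threshold.
#' @param min_cluster_voxels minimum cluster extent in voxels; if `NULL` it
#'   is derived by [alphasim_min_cluster()] inside the pipeline.
#' @param connectivity cluster connectivity: 6, 18 or 26.
#' @param dc_r_threshold correlation cutoff for degree centrality.
#' @param selector `"ttest"`, `"ttest+rfe"` or `"ttest+lasso"`.
#' @param classifier `"elm"`, `"svm_linear"` or `"svm_rbf"`.
#' @param cv list with `kind` (`"loo"` or `"kfold"`) and `k`.
#' @param k_grid candidate feature counts for RFE grid search; `NULL` uses a
#'   logarithmic grid capped at the feature count.
#' @param elm list with `L_grid` (hidden-node counts), `n_repeats`
#'   (random initialisations averaged per L; 100 by default) and
#'   `inner_folds`.
#' @param svm list with `C_grid` and `gamma_grid` (8-point decade grids by
#'   default) and `inner_folds`.
#' @param n_permutations label permutations for the significance test.
#' @param scale_maps z-score each measure map over the mask per subject
#'   before group statistics (cross-subject comparability).
#' @param rng_seed master seed; all stage seeds are derived from it via
#'   [substream_seed()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(band_hz = c(0.01, 0.08),
                       fwhm_mm = 6,
                       drop_initial = 0L,
                       alpha_voxel = 0.05,
                       alpha_cluster = 0.05,
                       min_cluster_voxels = NULL,
                       connectivity = 26,
                       dc_r_threshold = 0.25,
                       selector = c("ttest", "ttest+rfe", "ttest+lasso"),
                       classifier = c("elm", "svm_linear", "svm_rbf"),
                       cv = list(kind = "kfold", k = 10),
                       k_grid = NULL,
                       elm = list(L_grid = 1:400, n_repeats = 100,
                                  inner_folds = 5),
                       svm = list(C_grid = 10^(-3:4),
                                  gamma_grid = 10^(-3:4), inner_folds = 5),
                       n_permutations = 1000,
                       scale_maps = TRUE,
                       rng_seed = 1L) {
  selector <- match.arg(selector)
  classifier <- match.arg(classifier)
  stopifnot(length(band_hz) == 2L, band_hz[1] > 0, band_hz[2] > band_hz[1],
            fwhm_mm >= 0, alpha_voxel > 0, alpha_voxel < 1,
            alpha_cluster > 0, alpha_cluster < 1,
            connectivity %in% c(6, 18, 26),
            dc_r_threshold > -1, dc_r_threshold < 1,
            n_permutations >= 1)
  if (!cv$kind %in% c("loo", "kfold")) stop("cv$kind must be loo or kfold")
  if (cv$kind == "kfold" && (is.null(cv$k) || cv$k < 2))
    stop("kfold cv needs k >= 2")
  structure(list(band_hz = band_hz, fwhm_mm = fwhm_mm,
                 drop_initial = as.integer(drop_initial),
                 alpha_voxel = alpha_voxel, alpha_cluster = alpha_cluster,
                 min_cluster_voxels = min_cluster_voxels,
                 connectivity = connectivity,
                 dc_r_threshold = dc_r_threshold, selector = selector,
                 classifier = classifier, cv = cv, k_grid = k_grid,
                 elm = elm, svm = svm, n_permutations = n_permutations,
                 scale_maps = scale_maps, rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()]; unknown keys are an
#' error so typos never silently fall back to defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}
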
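# Outer cross-validation, the six performance metrics, and the label
# permutation significance test.

#' Confusion-count performance metrics
#'
#' The six standard binary metrics as percentages:
#' ACC = (TP+TN)/total, SEN = TP/(TP+FN), SPEC = TN/(TN+FP),
#' BAC = (SEN+SPEC)/2, PPV = TP/(TP+FP), NPV = TN/(TN+FN).
#' A zero denominator yields `NA` for that metric (flagged, never NaN
#' propagation); BAC needs both SEN and SPEC defined.
#'
#' @param tp,tn,fp,fn non-negative integer counts (total > 0). `tp` may
#'   also be a list/vector with named elements tp, tn, fp, fn.
#' @return A one-row tibble with columns TP, TN, FP, FN, ACC, SEN, SPEC,
#'   BAC, PPV, NPV and `n_undefined`.
#' @export
confusion_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn) && length(tp) == 4) {
    cc <- as.list(tp); tn <- cc$tn; fp <- cc$fp; fn <- cc$fn; tp <- cc$tp
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("negative confusion counts")
  total <- sum(counts)
  if (total == 0) stop("no test decisions (all counts zero)")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sen <- ratio(tp, tp + fn); spec <- ratio(tn, tn + fp)
  out <- tibble::tibble(
    TP = tp, TN = tn, FP = fp, FN = fn,
    ACC = 100 * (tp + tn) / total,
    SEN = sen, SPEC = spec,
    BAC = if (is.na(sen) || is.na(spec)) NA_real_ else (sen + spec) / 2,
    PPV = ratio(tp, tp + fp),
    NPV = ratio(tn, tn + fn))
  out$n_undefined <- sum(is.na(out[c("SEN", "SPEC", "BAC", "PPV", "NPV")]))
  out
}

#' Outer cross-validation of the full discrimination pipeline
#'
#' Per outer fold, strictly on training rows only: per-measure two-sample
#' t maps, the univariate cluster-corrected selection mask, feature
#' concatenation and train-statistics standardisation, optional SVM-RFE or
#' LASSO reduction, classifier hyperparameter search and fit; the held-out
#' rows are then predicted. Fold metrics are aggregated as mean +/- SD,
#' and pooled confusion counts are reported alongside.
#'
#' @param maps list over subjects of named measure-map lists (e.g. from
#'   [subject_measures()]).
#' @param mask the brain [mask_volume()].
#' @param labels 0/1 vector, 1 = positive (patient) class.
#' @param config a [run_config()]. `min_cluster_voxels = NULL` triggers a
#'   per-fold [alphasim_min_cluster()] run.
#' @param voxel_size_mm voxel size, used only by the per-fold Monte-Carlo
#'   cluster threshold when `min_cluster_voxels` is `NULL`.
#' @return An object of class `cv_result`: per-fold metrics tibble,
#'   pooled metrics, per-subject predictions, per-fold selection reports.
#' @export
cross_validate <- function(maps, mask, labels, config = run_config(),
                           voxel_size_mm = c(3, 3, 3)) {
  n <- length(maps)
  labels <- as.integer(labels)
  stopifnot(length(labels) == n, all(labels %in% 0:1))
  if (min(table(labels)) < 2) stop("need >= 2 subjects per class")
  folds <- if (config$cv$kind == "loo") seq_len(n)
           else stratified_folds(labels, config$cv$k,
                                 substream_seed(config$rng_seed, "cv"))
  n_folds <- max(folds)
  measures <- measure_order(names(maps[[1]]))

  fold_rows <- list(); sel_rows <- list()
  predictions <- tibble::tibble(subject = rownames_or_index(maps),
                                fold = folds, truth = labels,
                                pred = NA_integer_)
  models <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (length(unique(labels[tr])) < 2)
      stop("training fold ", f, " lost a class; use stratified kfold or ",
           "more subjects")
    t_maps <- lapply(stats::setNames(measures, measures), function(m)
      two_sample_t_map(lapply(tr[labels[tr] == 0], function(s) maps[[s]][[m]]),
                       lapply(tr[labels[tr] == 1], function(s) maps[[s]][[m]]),
                       mask))
    min_clust <- config$min_cluster_voxels %||%
      alphasim_min_cluster(mask, config$fwhm_mm, voxel_size_mm,
                           config$alpha_voxel, config$alpha_cluster,
                           n_iter = 1000, connectivity = config$connectivity,
                           seed = substream_seed(config$rng_seed,
                                                 "alphasim", f))
    um <- univariate_mask(t_maps, config$alpha_voxel, min_clust,
                          config$connectivity)
    fm_tr <- build_feature_matrix(maps[tr], um$masks, labels[tr])
    fm_te <- build_feature_matrix(maps[te], um$masks, labels[te])
    st <- standardize_fit(fm_tr$values)
    Xtr <- standardize_apply(fm_tr$values, st)
    Xte <- standardize_apply(fm_te$values, st)

    kept <- seq_len(ncol(Xtr))
    sel_seed <- substream_seed(config$rng_seed, "select", f)
    if (config$selector == "ttest+rfe" && ncol(Xtr) >= 2) {
      rfe <- svm_rfe_rank(Xtr, labels[tr])
      k_grid <- config$k_grid %||%
        unique(pmin(c(5, 10, 20, 40, 80, 160, 320), ncol(Xtr)))
      sel <- rfe_select_k(Xtr, labels[tr], rfe$ranking, k_grid,
                          seed = sel_seed)
      kept <- sel$kept
    } else if (config$selector == "ttest+lasso" && ncol(Xtr) >= 2) {
      sel <- lasso_select(Xtr, labels[tr], seed = sel_seed)$selection
      kept <- sel$kept
    }
    Xtr_k <- Xtr[, kept, drop = FALSE]
    Xte_k <- Xte[, kept, drop = FALSE]

    clf_seed <- substream_seed(config$rng_seed, "classifier", f)
    pred <- switch(
      config$classifier,
      elm = {
        gs <- elm_grid_search(Xtr_k, labels[tr],
                              L_grid = config$elm$L_grid,
                              n_repeats = config$elm$n_repeats,
                              inner_folds = config$elm$inner_folds,
                              seed = clf_seed)
        fit <- elm_train(Xtr_k, labels[tr], gs$best_L,
                         substream_seed(clf_seed, "elm_final"))
        models[[f]] <- list(type = "elm", L = gs$best_L, fit = fit)
        as.integer(elm_predict(fit, Xte_k) > 0)
      },
      svm_linear = ,
      svm_rbf = {
        kern <- if (config$classifier == "svm_linear") "linear" else "radial"
        gs <- svm_grid_search(Xtr_k, labels[tr], kernel = kern,
                              C_grid = config$svm$C_grid,
                              gamma_grid = config$svm$gamma_grid,
                              inner_folds = config$svm$inner_folds,
                              seed = clf_seed)
        models[[f]] <- list(type = kern, best = gs$best, fit = gs$model)
        as.integer(as.character(predict(gs$model, Xte_k)))
      })

    predictions$pred[te] <- pred
    cm <- confusion_metrics(tp = sum(pred == 1 & labels[te] == 1),
                            tn = sum(pred == 0 & labels[te] == 0),
                            fp = sum(pred == 1 & labels[te] == 0),
                            fn = sum(pred == 0 & labels[te] == 1))
    fold_rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), cm)
    sel_rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), um$report)
    sel_rows[[f]]$n_kept <- length(kept)
    attr(sel_rows[[f]], "kept") <- kept
    attr(sel_rows[[f]], "columns") <- fm_tr$columns
  }
  fold_metrics <- dplyr::bind_rows(fold_rows)
  pooled <- confusion_metrics(tp = sum(fold_metrics$TP),
                              tn = sum(fold_metrics$TN),
                              fp = sum(fold_metrics$FP),
                              fn = sum(fold_metrics$FN))
  structure(list(fold_metrics = fold_metrics, pooled = pooled,
                 predictions = predictions,
                 selections = sel_rows, models = models,
                 config = config), class = "cv_result")
}

rownames_or_index <- function(maps) {
  nm <- names(maps)
  if (is.null(nm)) paste0("sub", seq_along(maps)) else nm
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<cv_result> %d folds | mean ACC %.2f +/- %.2f %%, BAC %.2f %%\n",
    nrow(x$fold_metrics), g$ACC_mean, g$ACC_sd, g$BAC_mean))
  invisible(x)
}

#' Label permutation significance test
#'
#' Holds the per-subject test predictions fixed and permutes the true
#' labels `P` times; the null accuracy of each permutation is compared
#' with the observed accuracy and
#' `p = (1 + #(null >= observed)) / (1 + P)`. This follows the design of
#' permuting the test labels against fixed predictions; it tests the
#' labelling, not the full pipeline (see [cross_validate()] for the
#' stricter rerun variant discussed in the vignette).
#'
#' @param predictions predicted 0/1 labels (all test decisions).
#' @param truth true 0/1 labels.
#' @param n_permutations permutation count P (default 1000).
#' @param seed RNG seed.
#' @return An object of class `permutation_result` with `observed_acc`,
#'   `null_accs`, `p_value`.
#' @export
permutation_test <- function(predictions, truth, n_permutations = 1000,
                             seed = 1L) {
  stopifnot(length(predictions) == length(truth), n_permutations >= 1)
  observed <- mean(predictions == truth)
  null_accs <- with_seed(seed, vapply(seq_len(n_permutations), function(i)
    mean(predictions == sample(truth)), numeric(1)))
  p <- (1 + sum(null_accs >= observed)) / (1 + n_permutations)
  structure(list(observed_acc = observed, null_accs = null_accs,
                 p_value = p, P = n_permutations, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed accuracy %.3f, p = %.4g (P = %d)\n",
    x$observed_acc, x$p_value, x$P))
  invisible(x)
}
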
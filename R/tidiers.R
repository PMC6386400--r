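# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-fold metrics of a cross-validation result
#' @param x a `cv_result`.
#' @param ... unused.
#' @return Tibble with one row per outer fold.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$fold_metrics

#' Fold-averaged summary of a cross-validation result
#'
#' Mean +/- SD of each metric over folds (undefined fold metrics are
#' excluded and counted), plus pooled-count metrics.
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return A one-row tibble.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  fm <- x$fold_metrics
  out <- tibble::tibble(n_folds = nrow(fm))
  for (m in c("ACC", "SEN", "SPEC", "BAC", "PPV", "NPV")) {
    v <- fm[[m]]
    out[[paste0(m, "_mean")]] <- mean(v, na.rm = TRUE)
    out[[paste0(m, "_sd")]] <- if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE)
                               else 0
    out[[paste0(m, "_n_undefined")]] <- sum(is.na(v))
  }
  for (m in c("ACC", "SEN", "SPEC", "BAC", "PPV", "NPV"))
    out[[paste0(m, "_pooled")]] <- x$pooled[[m]]
  out
}

#' Coefficients of a LASSO fit at each lambda
#' @param x a `lasso_fit`.
#' @param ... unused.
#' @return Long tibble (lambda, term, estimate).
#' @method tidy lasso_fit
#' @export
tidy.lasso_fit <- function(x, ...) {
  q <- nrow(x$gamma)
  tibble::tibble(
    lambda = rep(x$lambda, each = q),
    term = rep(seq_len(q), times = length(x$lambda)),
    estimate = as.vector(x$gamma))
}

#' One-row summary of a LASSO fit
#' @param x a `lasso_fit`.
#' @param ... unused.
#' @return Tibble with lambda_max, chosen lambda and sparsity.
#' @method glance lasso_fit
#' @export
glance.lasso_fit <- function(x, ...) {
  li <- if (!is.null(x$lambda_opt)) which.min(abs(x$lambda - x$lambda_opt))
        else length(x$lambda)
  tibble::tibble(lambda_max = x$lambda_max,
                 lambda_opt = x$lambda_opt %||% NA_real_,
                 n_nonzero = sum(x$gamma[, li] != 0),
                 n_lambda = length(x$lambda))
}

#' Ranked features of a selection result
#' @param x a `selection_result`.
#' @param ... unused.
#' @return Tibble (feature, rank, kept).
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(feature = seq_along(x$ranking), rank = x$ranking,
                 kept = seq_along(x$ranking) %in% x$kept)
}

#' Summary of a permutation test
#' @param x a `permutation_result`.
#' @param ... unused.
#' @return One-row tibble.
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(observed_acc = x$observed_acc, p_value = x$p_value,
                 P = x$P, null_mean = mean(x$null_accs),
                 null_sd = sd(x$null_accs))
}

#' Plot per-fold cross-validation metrics
#' @param object a `cv_result`.
#' @param ... unused.
#' @return A ggplot: metric distribution over folds.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  fm <- object$fold_metrics
  long <- tibble::tibble(
    fold = rep(fm$fold, 6),
    metric = factor(rep(c("ACC", "SEN", "SPEC", "BAC", "PPV", "NPV"),
                        each = nrow(fm)),
                    levels = c("ACC", "SEN", "SPEC", "BAC", "PPV", "NPV")),
    value = c(fm$ACC, fm$SEN, fm$SPEC, fm$BAC, fm$PPV, fm$NPV))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "test metric (%)",
                  title = "Outer cross-validation performance") +
    ggplot2::theme_minimal()
}

#' Plot the cross-validated MSE curve of a LASSO fit
#' @param object a `lasso_fit` from [lasso_select()].
#' @param ... unused.
#' @return A ggplot of CV MSE against log10(lambda).
#' @method autoplot lasso_fit
#' @export
autoplot.lasso_fit <- function(object, ...) {
  if (is.null(object$cv_mse))
    stop("no CV curve; fit with lasso_select()")
  ggplot2::ggplot(object$cv_mse,
                  ggplot2::aes(x = log10(.data$lambda), y = .data$mse)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = log10(object$lambda_opt),
                        linetype = "dashed") +
    ggplot2::labs(x = "log10(lambda)", y = "cross-validated MSE",
                  title = "LASSO regularisation path") +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a measure map or t map
#'
#' @param map 3-D array (`measure_map` or plain).
#' @param slice z index; default middle slice.
#' @param title plot title; defaults to the measure name attribute.
#' @return A ggplot raster of the slice.
#' @export
plot_map_slice <- function(map, slice = NULL, title = NULL) {
  arr <- unclass(map)
  d <- dim(arr)
  stopifnot(length(d) == 3)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(arr[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title %||% attr(map, "measure"),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
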
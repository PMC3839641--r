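# broom-style tidiers for fitted objects and cross-validation results.

#' Tidy a fitted meta-classifier
#'
#' One row per feature with its random-forest importance (mean decrease in
#' Gini impurity).
#'
#' @param x A `"meta_fit"`.
#' @param ... Unused.
#' @return A tibble with `feature` and `importance`, in canonical feature
#'   order.
#' @exportS3Method generics::tidy
tidy.meta_fit <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble::tibble(feature = rownames(imp),
                 importance = as.numeric(imp[, 1]))
}

#' One-row summary of a fitted meta-classifier
#'
#' @param x A `"meta_fit"`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_disease`, `n_polymorphism`, `n_trees`,
#'   `mtry`, `oob_error` (the forest's out-of-bag error estimate).
#' @exportS3Method generics::glance
glance.meta_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_disease = as.integer(x$class_counts[["disease"]]),
    n_polymorphism = as.integer(x$class_counts[["polymorphism"]]),
    n_trees = x$config$n_trees,
    mtry = x$config$mtry,
    oob_error = x$forest$err.rate[x$config$n_trees, "OOB"]
  )
}

#' Per-variant out-of-fold predictions
#'
#' @param x A `"meta_cv"`.
#' @param ... Unused.
#' @return The prediction tibble: key columns, `label`, `fold`,
#'   `p_disease`, `call`, `ri`.
#' @exportS3Method generics::tidy
tidy.meta_cv <- function(x, ...) {
  x$predictions
}

#' One-row cross-validated performance summary
#'
#' @param x A `"meta_cv"`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_folds`, `q2`, `ppv`, `tpr`, `npv`, `tnr`,
#'   `mcc`, `auc`.
#' @exportS3Method generics::glance
glance.meta_cv <- function(x, ...) {
  rep <- evaluate_predictions(x$predictions)
  overall <- rep[rep$stratum == "overall", ]
  tibble::tibble(n = overall$n, n_folds = x$config$n_folds,
                 q2 = overall$q2, ppv = overall$ppv, tpr = overall$tpr,
                 npv = overall$npv, tnr = overall$tnr, mcc = overall$mcc,
                 auc = overall$auc)
}
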
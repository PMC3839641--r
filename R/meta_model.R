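# The random-forest meta-classifier: training, out-of-fold stratified
# cross-validation, probability prediction, the decision rule with its
# reliability index, and the accuracy/coverage trade-off over reliability
# cutoffs.

#' Meta-classifier configuration
#'
#' Collects the model hyperparameters and cross-validation protocol. The
#' canonical configuration is a 100-tree random forest over the 8-element
#' feature vector, 20-fold cross-validation stratified by class, and a 0.5
#' decision threshold on the disease probability. Features tried per split
#' default to `floor(log2(8) + 1) = 4`.
#'
#' @param n_trees Number of trees (>= 1).
#' @param n_folds Cross-validation folds (>= 2).
#' @param mtry Features tried per split.
#' @param decision_threshold Disease-call threshold on `p_disease`, in
#'   (0, 1).
#' @param fold_scheme `"variant"` (stratified by class at the variant
#'   level) or `"protein"` (all variants of a protein share a fold, to
#'   avoid homology leakage).
#' @param seed Integer seed making training and fold assignment
#'   reproducible.
#' @return A list of class `"model_config"`.
#' @export
model_config <- function(n_trees = 100, n_folds = 20, mtry = 4,
                         decision_threshold = 0.5,
                         fold_scheme = c("variant", "protein"), seed = 1L) {
  fold_scheme <- match.arg(fold_scheme)
  stopifnot(n_trees >= 1, n_folds >= 2,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(n_trees = as.integer(n_trees), n_folds = as.integer(n_folds),
                 mtry = as.integer(mtry),
                 decision_threshold = decision_threshold,
                 fold_scheme = fold_scheme, seed = as.integer(seed)),
            class = "model_config")
}

#' Train the random-forest meta-classifier
#'
#' Fits a random forest on complete 8-element feature vectors (see
#' [build_features()]) against disease/polymorphism labels. Training is
#' deterministic given `config$seed`, and a fitted model saved with
#' [write_meta_fit()] reloads to identical predictions.
#'
#' @param features Feature table containing the eight canonical feature
#'   columns (extra key columns are ignored).
#' @param labels True classes, one per row.
#' @param config A [model_config()].
#' @param registry Method registry recorded alongside the model for
#'   provenance.
#' @return An object of class `"meta_fit"`.
#' @export
meta_train <- function(features, labels, config = model_config(),
                       registry = method_registry()) {
  x <- feature_matrix(features)
  y <- as_disease_logical(labels)
  if (any(is.na(x))) rlang::abort("feature matrix contains missing values")
  if (any(is.na(y))) rlang::abort("labels contain missing values")
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    rlang::abort("need at least 2 examples per class to train")
  }
  yf <- factor(ifelse(y, "disease", "polymorphism"),
               levels = c("disease", "polymorphism"))
  set.seed(config$seed)
  forest <- randomForest::randomForest(
    x = x, y = yf, ntree = config$n_trees, mtry = config$mtry)
  structure(list(forest = forest, config = config, registry = registry,
                 n = nrow(x), class_counts = table(yf)),
            class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf(
    "Random-forest meta-classifier: %d trees, mtry %d, %d training variants (%d disease / %d polymorphism)\n",
    x$config$n_trees, x$config$mtry, x$n,
    x$class_counts[["disease"]], x$class_counts[["polymorphism"]]))
  invisible(x)
}

#' Disease probability from a fitted meta-classifier
#'
#' @param object A `"meta_fit"`.
#' @param newdata Feature table with the eight canonical columns.
#' @param ... Unused.
#' @return Numeric vector of `p_disease` in \[0, 1\] (the forest's vote
#'   fraction for the disease class).
#' @export
predict.meta_fit <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  unname(predict(object$forest, x, type = "prob")[, "disease"])
}

#' Binary call and reliability index from a disease probability
#'
#' The decision rule: a variant is called disease when
#' `p_disease > threshold` and polymorphism when `p_disease <= threshold`
#' (a probability exactly at the threshold is polymorphic). The
#' reliability index is `ri = 20 * |p_disease - 0.5|`, ranging 0 (no
#' confidence) to 10 (full confidence) for calls on either side.
#'
#' @param p_disease Probabilities in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return A tibble with `p_disease`, `call` (factor disease /
#'   polymorphism) and `ri`.
#' @export
classify_probability <- function(p_disease, threshold = 0.5) {
  if (any(is.na(p_disease)) || any(p_disease < 0 | p_disease > 1)) {
    rlang::abort("p_disease must lie in [0, 1]")
  }
  tibble::tibble(
    p_disease = p_disease,
    call = factor(ifelse(p_disease > threshold, "disease", "polymorphism"),
                  levels = c("disease", "polymorphism")),
    ri = 20 * abs(p_disease - 0.5)
  )
}

#' Predict variants with a fitted meta-classifier
#'
#' Convenience wrapper producing the full prediction record (probability,
#' call, reliability index) for a feature table, keyed like the input.
#'
#' @inheritParams predict.meta_fit
#' @param fit A `"meta_fit"`.
#' @param features Feature table (key columns carried through).
#' @return A tibble: variant key columns (if present) plus `p_disease`,
#'   `call`, `ri`.
#' @export
meta_predict <- function(fit, features) {
  p <- predict(fit, features)
  key <- intersect(VARIANT_KEY, names(features))
  dplyr::bind_cols(tibble::as_tibble(features)[, key, drop = FALSE],
                   classify_probability(p, fit$config$decision_threshold))
}

fold_assignment <- function(y, config, protein = NULL) {
  k <- config$n_folds
  fold <- integer(length(y))
  if (config$fold_scheme == "protein") {
    if (is.null(protein)) {
      rlang::abort("fold_scheme 'protein' requires protein ids")
    }
    prots <- unique(protein)
    set.seed(config$seed)
    prots <- sample(prots)
    pf <- stats::setNames(rep(seq_len(k), length.out = length(prots)), prots)
    fold <- unname(pf[protein])
  } else {
    set.seed(config$seed)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < k) {
        rlang::abort(sprintf(
          "class with %d examples cannot populate %d folds", length(idx), k))
      }
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  }
  fold
}

#' Out-of-fold cross-validation of the meta-classifier
#'
#' Splits the variants into `config$n_folds` folds (stratified by class
#' under the `"variant"` scheme, so fold sizes within each class differ by
#' at most one; grouped by protein under the `"protein"` scheme, so no
#' protein spans folds). Each fold is predicted by a forest trained on all
#' other folds, so every variant receives exactly one out-of-fold
#' probability from a model that never saw it. Fold assignment and each
#' per-fold fit are reproducible from `config$seed` (fold `i` trains with
#' seed `config$seed + i`).
#'
#' @inheritParams meta_train
#' @param protein Optional protein id per row (required for the
#'   `"protein"` fold scheme).
#' @return An object of class `"meta_cv"`: list with `predictions` (tibble:
#'   key columns, `label`, `fold`, `p_disease`, `call`, `ri`) and `config`.
#' @export
meta_cv <- function(features, labels, config = model_config(),
                    protein = NULL, registry = method_registry()) {
  features <- tibble::as_tibble(features)
  x <- feature_matrix(features)
  y <- as_disease_logical(labels)
  if (any(is.na(y))) rlang::abort("labels contain missing values")
  if (is.null(protein) && "protein_id" %in% names(features)) {
    protein <- features$protein_id
  }
  fold <- fold_assignment(y, config, protein)
  p <- rep(NA_real_, length(y))
  yf <- factor(ifelse(y, "disease", "polymorphism"),
               levels = c("disease", "polymorphism"))
  for (i in sort(unique(fold))) {
    test <- fold == i
    fit_cfg <- config
    fit_cfg$seed <- config$seed + i
    set.seed(fit_cfg$seed)
    forest <- randomForest::randomForest(
      x = x[!test, , drop = FALSE], y = yf[!test],
      ntree = config$n_trees, mtry = config$mtry)
    p[test] <- predict(forest, x[test, , drop = FALSE],
                       type = "prob")[, "disease"]
  }
  key <- intersect(VARIANT_KEY, names(features))
  preds <- dplyr::bind_cols(
    features[, key, drop = FALSE],
    tibble::tibble(label = yf, fold = fold),
    classify_probability(p, config$decision_threshold))
  structure(list(predictions = preds, config = config, registry = registry),
            class = "meta_cv")
}

#' @export
print.meta_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "%d-fold cross-validation, %d variants: Q2 %.3f, MCC %.3f, AUC %.3f\n",
    x$config$n_folds, g$n, g$q2, g$mcc, g$auc))
  invisible(x)
}

#' Accuracy/coverage trade-off over reliability-index cutoffs
#'
#' For each integer reliability cutoff 0..10, restricts to predictions with
#' `ri >= cutoff` and reports overall accuracy (Q2) and the fraction of
#' variants retained. The retained fraction is non-increasing in the
#' cutoff; raising the cutoff trades coverage for accuracy. Cutoffs that
#' retain no variants are flagged (`empty = TRUE`) rather than erroring.
#'
#' @param preds Prediction table with `call` and `ri` columns (e.g. from
#'   [meta_cv()]'s `predictions`).
#' @param labels True classes; defaults to `preds$label`.
#' @return A tibble: `ri_cutoff`, `n_retained`, `fraction_retained`, `q2`,
#'   `tpr`, `tnr`, `empty`.
#' @export
reliability_tradeoff <- function(preds, labels = NULL) {
  preds <- tibble::as_tibble(preds)
  if (is.null(labels)) labels <- preds$label
  y <- as_disease_logical(labels)
  purrr::map(0:10, function(cut) {
    keep <- preds$ri >= cut
    if (!any(keep)) {
      return(tibble::tibble(ri_cutoff = cut, n_retained = 0L,
                            fraction_retained = 0, q2 = NA_real_,
                            tpr = NA_real_, tnr = NA_real_, empty = TRUE))
    }
    cm <- confusion_matrix(y[keep], preds$call[keep])
    r <- classification_rates(cm)
    tibble::tibble(ri_cutoff = cut, n_retained = as.integer(sum(keep)),
                   fraction_retained = mean(keep), q2 = r$q2,
                   tpr = r$tpr, tnr = r$tnr, empty = FALSE)
  }) |> dplyr::bind_rows()
}

#' Serialize a fitted meta-classifier
#'
#' The artifact embeds the model configuration and method registry so a
#' reloaded model reproduces identical predictions and records its own
#' provenance.
#'
#' @param fit A `"meta_fit"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meta_fit <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' Reload a serialized meta-classifier
#'
#' @param path Path written by [write_meta_fit()].
#' @return The `"meta_fit"` object.
#' @export
read_meta_fit <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "meta_fit")) {
    rlang::abort("file does not contain a meta_fit object")
  }
  fit
}
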
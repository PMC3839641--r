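# Binary classification performance: confusion counts, accuracy and
# predictive values, Matthews correlation, ROC/AUC, and stratified reports.
# Positives are disease-associated variants; negatives are polymorphisms.

#' Confusion matrix of disease/polymorphism calls
#'
#' Tallies true/false positives and negatives, with disease as the positive
#' class: TP are correctly predicted disease variants, TN correctly
#' predicted polymorphisms, FP polymorphisms called disease, FN disease
#' variants called polymorphism.
#'
#' @param labels True classes: factor/character in
#'   `c("disease", "polymorphism")` or logical (`TRUE` = disease).
#' @param calls Predicted classes, same encoding.
#' @return A one-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(labels, calls) {
  labels <- as_disease_logical(labels)
  calls <- as_disease_logical(calls)
  if (length(labels) != length(calls)) {
    rlang::abort("labels and calls differ in length")
  }
  tibble::tibble(
    tp = sum(labels & calls),
    fp = sum(!labels & calls),
    tn = sum(!labels & !calls),
    fn = sum(labels & !calls)
  )
}

as_disease_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- as.character(x)
  pos <- x %in% c("disease", "damaging")
  neg <- x %in% c("polymorphism", "neutral")
  if (any(!pos & !neg & !is.na(x))) {
    rlang::abort("class vector contains values outside the binary encoding")
  }
  out <- rep(NA, length(x))
  out[pos] <- TRUE
  out[neg] <- FALSE
  out
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any
#' factor of the denominator is zero the coefficient is defined as 0
#' (standard convention for degenerate margins).
#'
#' @param cm Confusion matrix as returned by [confusion_matrix()] (any
#'   one-row data frame or named list with `tp`, `fp`, `tn`, `fn`).
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(cm) {
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  tn <- as.numeric(cm$tn); fn <- as.numeric(cm$fn)
  if (tp + fp + tn + fn == 0) {
    rlang::abort("all-zero confusion matrix")
  }
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den2)
}

#' Accuracy, predictive values and rates from a confusion matrix
#'
#' Computes overall accuracy `Q2 = (TP+TN)/total`, the positive and
#' negative predictive values `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`, the
#' true positive and negative rates `TPR = TP/(TP+FN)`,
#' `TNR = TN/(TN+FP)`, and [mcc()]. Rates with a zero denominator are
#' returned as `NA` (undefined), which is distinct from 0. Values are kept
#' at full precision; rounding to the conventional two decimals is left to
#' the presentation layer.
#'
#' @inheritParams mcc
#' @return A one-row tibble with columns `n`, `q2`, `ppv`, `tpr`, `npv`,
#'   `tnr`, `mcc`.
#' @export
classification_rates <- function(cm) {
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  tn <- as.numeric(cm$tn); fn <- as.numeric(cm$fn)
  total <- tp + fp + tn + fn
  if (total == 0) {
    rlang::abort("all-zero confusion matrix")
  }
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    n = as.integer(total),
    q2 = (tp + tn) / total,
    ppv = rate(tp, tp + fp),
    tpr = rate(tp, tp + fn),
    npv = rate(tn, tn + fn),
    tnr = rate(tn, tn + fp),
    mcc = mcc(cm)
  )
}

#' ROC curve and area under it
#'
#' Ranks variants by a disease score and computes the ROC curve (true
#' positive rate as a function of false positive rate over all distinct
#' score thresholds) and the area under it. The AUC is computed by the
#' midrank (concordance) formulation, `P(s+ > s-) + 0.5 P(s+ = s-)`, which
#' is exactly the trapezoidal area under the tie-aware threshold sweep.
#'
#' @param scores Numeric disease scores (higher = more disease-like).
#' @param labels True classes (see [confusion_matrix()]); both classes must
#'   be present.
#' @return An object of class `"roc_result"`: list with `auc` and `curve`
#'   (tibble of `threshold`, `tpr`, `fpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_disease_logical(labels)
  if (length(scores) != length(labels)) {
    rlang::abort("scores and labels differ in length")
  }
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("both classes must be present to compute a ROC curve")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    tpr = c(0, purrr::map_dbl(thr, ~ sum(labels & scores >= .x) / n_pos)),
    fpr = c(0, purrr::map_dbl(thr, ~ sum(!labels & scores >= .x) / n_neg))
  )
  structure(list(auc = auc, curve = curve,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d disease, %d polymorphism)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Performance report for labeled predictions, overall and per stratum
#'
#' Builds a confusion matrix and the full rate panel (plus AUC when
#' probabilities are available) for the whole prediction set and, when a
#' stratification is given, for each stratum on exactly that stratum's
#' variants. Empty strata are reported with `NA` metrics and flagged in the
#' `empty` column rather than raising an error.
#'
#' @param preds A data frame with a `call` column and optionally
#'   `p_disease` (for AUC).
#' @param labels True classes, recycled from `preds$label` if absent.
#' @param strata Optional factor/character stratum tag per variant (e.g.
#'   the consensus/majority/tie subset).
#' @return A tibble with one row per stratum plus an `"overall"` row:
#'   `stratum`, `n`, `q2`, `ppv`, `tpr`, `npv`, `tnr`, `mcc`, `auc`,
#'   `empty`.
#' @export
evaluate_predictions <- function(preds, labels = NULL, strata = NULL) {
  preds <- tibble::as_tibble(preds)
  if (is.null(labels)) {
    if (!"label" %in% names(preds)) {
      rlang::abort("no labels supplied and no 'label' column present")
    }
    labels <- preds$label
  }
  if (all(is.na(labels))) {
    rlang::abort("labels are all missing; cannot evaluate")
  }
  if (is.null(strata) && "subset" %in% names(preds)) strata <- preds$subset
  one <- function(idx, tag) {
    if (length(idx) == 0) {
      return(tibble::tibble(stratum = tag, n = 0L, q2 = NA_real_,
                            ppv = NA_real_, tpr = NA_real_, npv = NA_real_,
                            tnr = NA_real_, mcc = NA_real_, auc = NA_real_,
                            empty = TRUE))
    }
    cm <- confusion_matrix(labels[idx], preds$call[idx])
    rates <- classification_rates(cm)
    auc <- NA_real_
    if ("p_disease" %in% names(preds)) {
      lab <- as_disease_logical(labels[idx])
      if (length(unique(lab)) == 2) {
        auc <- roc_auc(preds$p_disease[idx], labels[idx])$auc
      }
    }
    dplyr::bind_cols(tibble::tibble(stratum = tag), rates,
                     tibble::tibble(auc = auc, empty = FALSE))
  }
  out <- one(seq_len(nrow(preds)), "overall")
  if (!is.null(strata)) {
    levs <- if (is.factor(strata)) levels(strata) else sort(unique(strata))
    per <- purrr::map(levs, ~ one(which(strata == .x), .x))
    out <- dplyr::bind_rows(out, per)
  }
  out
}

#' Round a performance report for presentation
#'
#' @param report Output of [evaluate_predictions()] or
#'   [classification_rates()].
#' @param digits Decimal places (default 2, the conventional table
#'   precision).
#' @return The report with metric columns rounded.
#' @export
format_report <- function(report, digits = 2) {
  dplyr::mutate(report, dplyr::across(
    dplyr::any_of(c("q2", "ppv", "tpr", "npv", "tnr", "mcc", "auc")),
    ~ round(.x, digits)))
}
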
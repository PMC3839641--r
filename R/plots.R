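# ggplot2 visualisations of the main result types.

#' ROC curve plot
#'
#' @param object A `"roc_result"` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot: TPR as a function of FPR, with the chance diagonal.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Cross-validation result plot
#'
#' ROC curve of the out-of-fold disease probabilities.
#'
#' @param object A `"meta_cv"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.meta_cv <- function(object, ...) {
  preds <- object$predictions
  autoplot(roc_auc(preds$p_disease, preds$label))
}

#' Accuracy/coverage trade-off plot over reliability cutoffs
#'
#' @param tradeoff Output of [reliability_tradeoff()].
#' @return A ggplot of Q2 and retained fraction against the RI cutoff.
#' @export
plot_reliability_tradeoff <- function(tradeoff) {
  long <- tidyr::pivot_longer(
    tradeoff[!tradeoff$empty, c("ri_cutoff", "q2", "fraction_retained")],
    cols = c("q2", "fraction_retained"),
    names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ri_cutoff, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 0:10) +
    ggplot2::labs(x = "Reliability-index cutoff", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Class-conditional feature-distribution plot
#'
#' Mirrors the histogram panels used to compare disease and polymorphism
#' profile-feature distributions within each agreement subset.
#'
#' @param distributions Output of [feature_distributions()].
#' @return A ggplot faceted by subset and feature.
#' @export
plot_feature_distributions <- function(distributions) {
  h <- tidyr::pivot_longer(distributions$histograms,
                           cols = c("prop_disease", "prop_polymorphism"),
                           names_to = "class", names_prefix = "prop_",
                           values_to = "proportion")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_lo, y = .data$proportion,
                                  fill = .data$class)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5,
                      width = h$bin_hi[1] - h$bin_lo[1], just = 0) +
    ggplot2::facet_grid(subset ~ feature) +
    ggplot2::labs(x = "Feature value", y = "Proportion", fill = NULL) +
    ggplot2::theme_minimal()
}
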
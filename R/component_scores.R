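# Interpretation of the four component predictors' raw outputs: native
# scales, decision thresholds, polarity of the damaging side, imputation
# defaults, binarization, and assembly of the 8-element meta feature vector.

#' Component-method registry
#'
#' One row per component predictor, giving its native score range, the
#' decision threshold on that scale, the polarity of the damaging side, and
#' the value imputed when the method returns no prediction. The shipped
#' defaults encode the canonical configuration: PhD-SNP and PANTHER are
#' probabilities in \[0, 1\] with scores above 0.5 indicating disease/damage;
#' SIFT is a normalized score in \[0, 1\] where scores below 0.05 are
#' deleterious; SNAP is a raw score in \[-100, 100\] where scores above 0 are
#' non-neutral. Each method's imputation default sits exactly at its
#' threshold, so an imputed score always binarizes to a neutral call.
#'
#' @param methods Character vector of method names to include, a subset of
#'   the four canonical methods. Keep the default for the standard
#'   meta-predictor configuration.
#' @return A tibble with columns `method`, `threshold`, `polarity`
#'   (`"gt"` if scores greater than the threshold are damaging, `"lt"` if
#'   scores less than it are), `default` (imputation value), `lower`,
#'   `upper` (documented score range).
#' @examples
#' method_registry()
#' @export
method_registry <- function(methods = METHODS) {
  reg <- tibble::tibble(
    method    = METHODS,
    threshold = c(0.5, 0.5, 0.05, 0),
    polarity  = c("gt", "gt", "lt", "gt"),
    default   = c(0.5, 0.5, 0.05, 0),
    lower     = c(0, 0, 0, -100),
    upper     = c(1, 1, 1, 100)
  )
  unknown <- setdiff(methods, reg$method)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown method(s): ", paste(unknown, collapse = ", ")))
  }
  reg[match(methods, reg$method), ]
}

#' Custom method specification
#'
#' Declare an additional component predictor for an extended registry. The
#' canonical meta-predictor uses exactly the four built-in methods, but the
#' binarization and similarity machinery accepts any registry built from
#' specs.
#'
#' @param name Method identifier.
#' @param threshold Decision cutoff on the method's native scale.
#' @param polarity `"gt"` or `"lt"`: side of the threshold that is damaging.
#' @param default Value imputed when the method returns no prediction;
#'   conventionally equal to `threshold` so imputed calls are neutral.
#' @param lower,upper Documented native score range.
#' @return A one-row tibble with the same columns as [method_registry()].
#' @export
method_spec <- function(name, threshold, polarity = c("gt", "lt"),
                        default = threshold, lower = -Inf, upper = Inf) {
  polarity <- match.arg(polarity)
  tibble::tibble(method = name, threshold = threshold, polarity = polarity,
                 default = default, lower = lower, upper = upper)
}

method_cols <- function(scores, registry) {
  intersect(registry$method, names(scores))
}

#' Impute missing component scores
#'
#' Replaces each missing (`NA`) component score with the method's default
#' imputation value: SNAP 0, SIFT 0.05, PhD-SNP 0.5, PANTHER 0.5. Each
#' default equals the method's decision threshold, so imputed scores
#' binarize to neutral calls. Present scores are left bit-identical and the
#' operation is idempotent.
#'
#' @param scores A data frame with one row per variant and one numeric
#'   column per method (missing predictions as `NA`); any other columns
#'   (e.g. the variant key) are passed through untouched.
#' @param registry Method registry, see [method_registry()].
#' @return A tibble of the same shape with no missing scores in the method
#'   columns.
#' @examples
#' impute_scores(tibble::tibble(panther = NA_real_, phdsnp = 0.9,
#'                              sift = NA_real_, snap = 12))
#' @export
impute_scores <- function(scores, registry = method_registry()) {
  scores <- tibble::as_tibble(scores)
  for (m in method_cols(scores, registry)) {
    default <- registry$default[registry$method == m]
    scores[[m]][is.na(scores[[m]])] <- default
  }
  scores
}

#' Binarize a native-scale score into a damaging/neutral call
#'
#' A score is called damaging only if it lies strictly on the damaging side
#' of the method's threshold (`> threshold` for `"gt"` polarity, `<` for
#' `"lt"`); a score exactly at the threshold is neutral. This strict
#' convention makes imputed defaults (which sit at the threshold) yield
#' neutral calls for every method.
#'
#' @param method Method name present in `registry`.
#' @param score Numeric vector of native-scale scores (`NA` allowed;
#'   propagates).
#' @param registry Method registry.
#' @return Factor vector with levels `c("damaging", "neutral")`.
#' @examples
#' binarize("sift", c(0.03, 0.05, 0.9))
#' binarize("snap", c(-5, 0, 17))
#' @export
binarize <- function(method, score, registry = method_registry()) {
  row <- registry[registry$method == method, ]
  if (nrow(row) != 1) {
    rlang::abort(paste0("unknown method: ", method))
  }
  damaging <- if (row$polarity == "gt") score > row$threshold else score < row$threshold
  factor(ifelse(damaging, "damaging", "neutral"),
         levels = c("damaging", "neutral"))
}

#' Binarize a score table into a call table
#'
#' Applies [binarize()] to each method column. Missing scores produce `NA`
#' calls unless imputed first (see [impute_scores()]).
#'
#' @inheritParams impute_scores
#' @return A tibble with the method columns replaced by factor calls.
#' @export
binarize_scores <- function(scores, registry = method_registry()) {
  scores <- tibble::as_tibble(scores)
  for (m in method_cols(scores, registry)) {
    scores[[m]] <- binarize(m, scores[[m]], registry)
  }
  scores
}

#' Per-method native prediction coverage
#'
#' Fraction of variants for which each method returned a native
#' (non-imputed) prediction — the "%DB" notion used when benchmarking
#' component predictors, some of which return no output when no suitable
#' family model or alignment is found.
#'
#' @inheritParams impute_scores
#' @return A tibble with columns `method`, `n`, `n_native`, `coverage`.
#' @export
score_coverage <- function(scores, registry = method_registry()) {
  scores <- tibble::as_tibble(scores)
  cols <- method_cols(scores, registry)
  if (nrow(scores) == 0) {
    rlang::abort("empty score table: coverage is undefined")
  }
  tibble::tibble(
    method   = cols,
    n        = nrow(scores),
    n_native = purrr::map_int(cols, ~ sum(!is.na(scores[[.x]]))),
  ) |>
    dplyr::mutate(coverage = .data$n_native / .data$n)
}

validate_score_ranges <- function(scores, registry = method_registry()) {
  for (m in method_cols(scores, registry)) {
    row <- registry[registry$method == m, ]
    bad <- which(!is.na(scores[[m]]) &
                   (scores[[m]] < row$lower | scores[[m]] > row$upper))
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "score out of range for method '%s' (allowed [%g, %g]) at row(s): %s",
        m, row$lower, row$upper, paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  invisible(scores)
}

#' Assemble the 8-element meta feature vector(s)
#'
#' Joins component scores with sequence-profile features into the fixed
#' feature layout consumed by the meta-classifier:
#' `panther, phdsnp, sift, snap, f_wt, f_mut, n_al, ci`. Missing component
#' scores are imputed first ([impute_scores()]); scores enter raw — neither
#' binarized nor rescaled (tree ensembles are invariant to monotone feature
#' scaling, so SNAP keeps its native \[-100, 100\] range). The result is a
#' pure function of its inputs.
#'
#' @param scores Score table keyed by `protein_id`, `position`, `wt`, `mut`
#'   with the four method columns (`NA` for missing predictions).
#' @param profiles Profile-feature table with the same key and columns
#'   `f_wt`, `f_mut`, `n_al`, `ci` (see [profile_features()]); must be
#'   complete for every variant in `scores`.
#' @param registry Method registry.
#' @return A tibble with the variant key followed by the eight feature
#'   columns in canonical order.
#' @export
build_features <- function(scores, profiles, registry = method_registry()) {
  scores <- tibble::as_tibble(scores)
  profiles <- tibble::as_tibble(profiles)
  key <- intersect(VARIANT_KEY, intersect(names(scores), names(profiles)))
  if (length(key) == 0) {
    rlang::abort("scores and profiles share no key columns")
  }
  validate_score_ranges(scores, registry)
  out <- impute_scores(scores, registry) |>
    dplyr::left_join(profiles[, c(key, c("f_wt", "f_mut", "n_al", "ci"))],
                     by = key)
  prof_cols <- c("f_wt", "f_mut", "n_al", "ci")
  incomplete <- !stats::complete.cases(out[, prof_cols])
  if (any(incomplete)) {
    rlang::abort(sprintf(
      "incomplete profile features for %d variant(s), e.g. row %d",
      sum(incomplete), which(incomplete)[1]))
  }
  out[, c(key, FEATURES)]
}

#' Extract the bare feature matrix from a feature table
#'
#' @param features Output of [build_features()] (or any data frame
#'   containing the eight canonical feature columns).
#' @return A numeric matrix with columns in canonical feature order.
#' @keywords internal
feature_matrix <- function(features) {
  missing <- setdiff(FEATURES, names(features))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing feature column(s): ",
                        paste(missing, collapse = ", ")))
  }
  as.matrix(features[, FEATURES])
}
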
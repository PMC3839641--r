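# Predictor-agreement stratification (consensus / majority / tie), pairwise
# method similarity (prediction overlap and correlation), UPGMA trees over
# method distances, and class-conditional feature-distribution overlap.

SUBSETS <- c("consensus", "majority", "tie")

#' Agreement stratum of four binary calls
#'
#' Classifies the split of the four component calls: 4-0 (all agree) is
#' `consensus`, 3-1 is `majority`, 2-2 is `tie`.
#'
#' @param calls Vector of exactly four calls in
#'   `c("damaging", "neutral")`.
#' @return One of `"consensus"`, `"majority"`, `"tie"` (factor).
#' @export
stratum <- function(calls) {
  if (length(calls) != 4 || any(is.na(calls))) {
    rlang::abort("exactly four non-missing calls are required")
  }
  d <- sum(as.character(calls) == "damaging")
  lab <- switch(as.character(min(d, 4 - d)),
                "0" = "consensus", "1" = "majority", "2" = "tie")
  factor(lab, levels = SUBSETS)
}

#' Stratify a call table by predictor agreement
#'
#' Adds a `subset` column giving each variant's agreement stratum from its
#' four binarized component calls. By default, calls derived from imputed
#' (at-threshold, hence neutral) scores participate, so every variant is
#' stratified; set `drop_imputed = TRUE` and supply the raw `scores` to
#' exclude variants for which any method's prediction was imputed
#' (sensitivity analysis).
#'
#' @param calls A data frame with the four method call columns (see
#'   [binarize_scores()]); no missing calls allowed.
#' @param drop_imputed Exclude variants whose raw scores had any missing
#'   method prediction.
#' @param scores Raw (pre-imputation) score table, required when
#'   `drop_imputed = TRUE`.
#' @param registry Method registry.
#' @return `calls` with an added factor column `subset` (rows possibly
#'   dropped when `drop_imputed = TRUE`).
#' @export
stratify_calls <- function(calls, drop_imputed = FALSE, scores = NULL,
                           registry = method_registry()) {
  calls <- tibble::as_tibble(calls)
  cols <- method_cols(calls, registry)
  if (length(cols) != 4) {
    rlang::abort("call table must contain the four method columns")
  }
  if (drop_imputed) {
    if (is.null(scores)) {
      rlang::abort("drop_imputed = TRUE requires the raw score table")
    }
    keep <- stats::complete.cases(scores[, cols])
    calls <- calls[keep, ]
  }
  m <- sapply(calls[, cols], function(x) as.character(x) == "damaging")
  m <- matrix(m, ncol = length(cols))
  if (any(is.na(m))) {
    rlang::abort("missing calls: impute scores before stratifying")
  }
  d <- rowSums(m)
  agree <- pmin(d, 4 - d)
  calls$subset <- factor(SUBSETS[agree + 1], levels = SUBSETS)
  calls
}

#' Subset sizes and fractions of a stratified dataset
#'
#' @param stratified Output of [stratify_calls()] (any data frame with a
#'   `subset` column).
#' @return A tibble with `subset`, `n`, `fraction`; fractions sum to 1.
#' @export
partition_fractions <- function(stratified) {
  tab <- table(factor(stratified$subset, levels = SUBSETS))
  tibble::tibble(
    subset = factor(SUBSETS, levels = SUBSETS),
    n = as.integer(tab),
    fraction = as.integer(tab) / sum(tab)
  )
}

#' Pairwise similarity between two methods' calls
#'
#' Overlap is the fraction of variants on which the two methods make the
#' same binary call; the correlation is the Matthews coefficient of the
#' 2x2 agreement table, treating the first method's calls as reference
#' labels (it is symmetric in the pair).
#'
#' @param calls_a,calls_b Call vectors in `c("damaging", "neutral")`, same
#'   length; pairs with a missing call in either vector are dropped.
#' @return A one-row tibble with `n_common`, `overlap`, `mcc`.
#' @export
pairwise_similarity <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    rlang::abort("call vectors differ in length")
  }
  a <- as_disease_logical(as.character(calls_a))
  b <- as_disease_logical(as.character(calls_b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) {
    rlang::abort("empty intersection: no variants predicted by both methods")
  }
  cm <- tibble::tibble(tp = sum(a & b), fp = sum(!a & b),
                       tn = sum(!a & !b), fn = sum(a & !b))
  tibble::tibble(n_common = length(a), overlap = mean(a == b), mcc = mcc(cm))
}

#' Similarity matrix across all method pairs
#'
#' Computes [pairwise_similarity()] for every ordered pair of methods. With
#' `restrict_to_common = TRUE` (the default) each pair is compared only on
#' the variants natively predicted by both methods, as judged from the raw
#' (pre-imputation) score table; otherwise the supplied calls are compared
#' wherever both are non-missing.
#'
#' @param calls Call table with the method columns (see
#'   [binarize_scores()]).
#' @param scores Raw score table; required for `restrict_to_common`.
#' @param restrict_to_common Restrict each pair to variants with native
#'   predictions from both methods.
#' @param registry Method registry.
#' @return A tibble with `method_a`, `method_b`, `n_common`, `overlap`,
#'   `mcc` covering all pairs (diagonal included: overlap 1, mcc 1).
#' @export
similarity_matrix <- function(calls, scores = NULL,
                              restrict_to_common = TRUE,
                              registry = method_registry()) {
  calls <- tibble::as_tibble(calls)
  cols <- method_cols(calls, registry)
  if (restrict_to_common && is.null(scores)) {
    rlang::abort("restrict_to_common = TRUE requires the raw score table")
  }
  pairs <- expand.grid(method_a = cols, method_b = cols,
                       stringsAsFactors = FALSE)
  out <- purrr::pmap(pairs, function(method_a, method_b) {
    ca <- calls[[method_a]]; cb <- calls[[method_b]]
    if (restrict_to_common) {
      keep <- !is.na(scores[[method_a]]) & !is.na(scores[[method_b]])
      ca <- ca[keep]; cb <- cb[keep]
    }
    dplyr::bind_cols(tibble::tibble(method_a = method_a, method_b = method_b),
                     pairwise_similarity(ca, cb))
  })
  dplyr::bind_rows(out)
}

#' UPGMA tree over a method distance matrix
#'
#' Standard unweighted pair-group agglomeration with arithmetic mean
#' linkage; the result is ultrametric (every leaf is equidistant from the
#' root). Distances are typically `1 - overlap` or `(1 - mcc) / 2` from
#' [similarity_matrix()]; see [similarity_tree()] for that convenience.
#'
#' @param d Symmetric numeric matrix with zero diagonal and row/column
#'   names, or a [stats::dist] object.
#' @return An [ape::as.phylo()] tree with branch lengths.
#' @export
upgma_tree <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d)) || any(diag(d) != 0)) {
      rlang::abort("distance matrix must be symmetric with zero diagonal")
    }
    d <- stats::as.dist(d)
  }
  hc <- stats::hclust(d, method = "average")
  ape::as.phylo(hc)
}

#' UPGMA tree from a pairwise similarity table
#'
#' @param sim Output of [similarity_matrix()].
#' @param metric Distance source: `1 - overlap` or the correlation rescaled
#'   to a distance, `(1 - mcc) / 2`.
#' @param path Optional path to also serialize the tree in Newick
#'   (parenthesized) format.
#' @return An `ape` phylo tree.
#' @export
similarity_tree <- function(sim, metric = c("overlap", "mcc"), path = NULL) {
  metric <- match.arg(metric)
  methods <- unique(sim$method_a)
  d <- matrix(0, length(methods), length(methods),
              dimnames = list(methods, methods))
  for (i in seq_len(nrow(sim))) {
    val <- if (metric == "overlap") 1 - sim$overlap[i] else (1 - sim$mcc[i]) / 2
    d[sim$method_a[i], sim$method_b[i]] <- val
  }
  diag(d) <- 0
  tree <- upgma_tree(d)
  if (!is.null(path)) ape::write.tree(tree, path)
  tree
}

#' Class-conditional feature distributions per agreement subset
#'
#' Bins the profile features (`f_wt`, `f_mut`, `ci`, all on \[0, 1\]) into
#' fixed-width bins, separately for disease and polymorphism variants
#' within each agreement subset, and reports the histogram overlap
#' coefficient (sum of bin-wise minima of the two class proportions, in
#' \[0, 1\]): 1 for identical distributions, 0 for disjoint supports. The
#' degree of class separation in these features is what distinguishes the
#' easy (consensus) from the hard (tie) variants.
#'
#' @param profiles Profile-feature table (see [profile_features()]).
#' @param labels True classes per row of `profiles`.
#' @param subsets Agreement stratum per row (from [stratify_calls()]);
#'   `NULL` for a single overall stratum.
#' @param features Which feature columns to compare.
#' @param binwidth Bin width on \[0, 1\] (default 0.05).
#' @return A list with `histograms` (tibble: `subset`, `feature`, `bin_lo`,
#'   `bin_hi`, `prop_disease`, `prop_polymorphism`) and `overlap` (tibble:
#'   `subset`, `feature`, `overlap`).
#' @export
feature_distributions <- function(profiles, labels, subsets = NULL,
                                  features = c("f_wt", "f_mut", "ci"),
                                  binwidth = 0.05) {
  profiles <- tibble::as_tibble(profiles)
  labels <- as_disease_logical(labels)
  if (is.null(subsets)) subsets <- factor(rep("overall", nrow(profiles)))
  subsets <- as.factor(subsets)
  breaks <- seq(0, 1, by = binwidth)
  if (abs(breaks[length(breaks)] - 1) > 1e-12) breaks <- c(breaks, 1)
  hist_rows <- list(); ov_rows <- list()
  for (s in levels(subsets)) {
    idx <- which(subsets == s)
    if (length(idx) == 0) {
      rlang::abort(paste0("empty subset: ", s))
    }
    for (f in features) {
      x <- profiles[[f]][idx]; y <- labels[idx]
      bin <- function(v) {
        if (length(v) == 0) return(rep(0, length(breaks) - 1))
        h <- graphics::hist(pmin(pmax(v, 0), 1), breaks = breaks,
                            plot = FALSE, include.lowest = TRUE)
        h$counts / length(v)
      }
      pd <- bin(x[y]); pp <- bin(x[!y])
      hist_rows[[length(hist_rows) + 1]] <- tibble::tibble(
        subset = s, feature = f,
        bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
        prop_disease = pd, prop_polymorphism = pp)
      ov_rows[[length(ov_rows) + 1]] <- tibble::tibble(
        subset = s, feature = f, overlap = sum(pmin(pd, pp)))
    }
  }
  list(histograms = dplyr::bind_rows(hist_rows),
       overlap = dplyr::bind_rows(ov_rows))
}
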
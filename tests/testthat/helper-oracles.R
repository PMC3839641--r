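# Independent brute-force oracles used to check the fast implementations.

# AUC as pairwise concordance: P(s+ > s-) + 0.5 P(s+ = s-), O(n^2)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "disease"]
  neg <- scores[labels != "disease"]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# UPGMA by explicit agglomeration over leaf sets, recomputing the
# unweighted average linkage from the original matrix at every step;
# returns the implied ultrametric (cophenetic) distance matrix
upgma_cophenetic_oracle <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_val <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        val <- mean(d[clusters[[i]], clusters[[j]]])
        if (val < best_val) {
          best_val <- val
          best <- c(i, j)
        }
      }
    }
    for (a in clusters[[best[1]]]) {
      for (b in clusters[[best[2]]]) {
        coph[a, b] <- coph[b, a] <- best_val
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  coph
}

# per-row agreement stratum by direct counting
stratum_oracle <- function(calls) {
  d <- sum(calls == "damaging")
  c("consensus", "majority", "tie")[min(d, 4 - d) + 1]
}

random_call_table <- function(n, seed) {
  set.seed(seed)
  tbl <- tibble::tibble(
    panther = sample(c("damaging", "neutral"), n, replace = TRUE),
    phdsnp = sample(c("damaging", "neutral"), n, replace = TRUE),
    sift = sample(c("damaging", "neutral"), n, replace = TRUE),
    snap = sample(c("damaging", "neutral"), n, replace = TRUE)
  )
  dplyr::mutate(tbl, dplyr::across(
    dplyr::everything(),
    ~ factor(.x, levels = c("damaging", "neutral"))))
}

label_factor <- function(x) {
  factor(ifelse(x, "disease", "polymorphism"),
         levels = c("disease", "polymorphism"))
}

# balanced-design confusion counts from printed per-class rates
cm_from_rates <- function(n_per_class, tpr, tnr) {
  tibble::tibble(
    tp = round(tpr * n_per_class),
    fn = n_per_class - round(tpr * n_per_class),
    tn = round(tnr * n_per_class),
    fp = n_per_class - round(tnr * n_per_class)
  )
}

# per-method AUC of the native scores, oriented so damaging is high
component_aucs <- function(scores, labels, registry = method_registry()) {
  sapply(registry$method, function(m) {
    x <- scores[[m]]
    keep <- !is.na(x)
    oriented <- if (registry$polarity[registry$method == m] == "lt") {
      -x[keep]
    } else {
      x[keep]
    }
    roc_auc(oriented, labels[keep])$auc
  })
}
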
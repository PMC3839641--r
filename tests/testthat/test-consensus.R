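call_fct <- function(x) factor(x, levels = c("damaging", "neutral"))

test_that("agreement strata follow the 4-0 / 3-1 / 2-2 rule", {
  expect_equal(as.character(stratum(call_fct(rep("damaging", 4)))), "consensus")
  expect_equal(as.character(stratum(call_fct(rep("neutral", 4)))), "consensus")
  expect_equal(as.character(
    stratum(call_fct(c("damaging", "damaging", "damaging", "neutral")))),
    "majority")
  expect_equal(as.character(
    stratum(call_fct(c("damaging", "damaging", "neutral", "neutral")))),
    "tie")
  expect_error(stratum(call_fct(c("damaging", "neutral"))), "four")
})

test_that("dataset stratification matches a row-by-row oracle and partitions the data", {
  calls <- random_call_table(300, seed = 5)
  strat <- stratify_calls(calls)
  oracle <- apply(as.matrix(calls), 1, stratum_oracle)
  expect_equal(as.character(strat$subset), oracle)
  fr <- partition_fractions(strat)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(sum(fr$n), nrow(calls))

  # degenerate tables
  allsame <- tibble::tibble(panther = call_fct(rep("damaging", 10)),
                            phdsnp = call_fct(rep("damaging", 10)),
                            sift = call_fct(rep("damaging", 10)),
                            snap = call_fct(rep("damaging", 10)))
  fr2 <- partition_fractions(stratify_calls(allsame))
  expect_equal(fr2$fraction[fr2$subset == "consensus"], 1)
  threeone <- dplyr::mutate(allsame, snap = call_fct(rep("neutral", 10)))
  fr3 <- partition_fractions(stratify_calls(threeone))
  expect_equal(fr3$fraction[fr3$subset == "majority"], 1)
})

test_that("stratification can exclude variants with imputed calls", {
  fx <- worked_fixture()
  calls <- binarize_scores(impute_scores(fx$scores))
  full <- stratify_calls(calls)
  expect_equal(nrow(full), 12)
  expect_equal(as.integer(table(full$subset)), c(4L, 4L, 4L))
  native_only <- stratify_calls(calls, drop_imputed = TRUE,
                                scores = fx$scores)
  expect_equal(nrow(native_only), 8)  # one missing score per method
  expect_error(stratify_calls(calls, drop_imputed = TRUE), "raw score")
  expect_error(stratify_calls(binarize_scores(fx$scores)), "impute")
})

test_that("pairwise similarity reproduces hand-computed contingencies", {
  a <- call_fct(rep(c("damaging", "neutral"), c(6, 4)))
  expect_equal(pairwise_similarity(a, a),
               tibble::tibble(n_common = 10L, overlap = 1, mcc = 1))
  flipped <- call_fct(ifelse(a == "damaging", "neutral", "damaging"))
  ps <- pairwise_similarity(a, flipped)
  expect_equal(ps$overlap, 0)
  expect_equal(ps$mcc, -1)

  # 2x2 agreement table 40/10/10/40
  b <- call_fct(rep(c("damaging", "neutral", "damaging", "neutral"),
                    c(40, 10, 10, 40)))
  c2 <- call_fct(rep(c("damaging", "neutral"), c(50, 50)))
  ps2 <- pairwise_similarity(b, c2)
  expect_equal(ps2$overlap, 0.8)
  expect_equal(ps2$mcc, 0.6)
  # symmetry
  expect_equal(ps2, pairwise_similarity(c2, b))

  expect_error(pairwise_similarity(call_fct(NA), call_fct("damaging")),
               "empty intersection")
})

test_that("similarity matrices restrict pairs to commonly predicted variants", {
  fx <- worked_fixture()
  calls <- binarize_scores(impute_scores(fx$scores))
  sim <- similarity_matrix(calls, fx$scores, restrict_to_common = TRUE)
  expect_equal(nrow(sim), 16)
  diag_rows <- sim[sim$method_a == sim$method_b, ]
  expect_true(all(diag_rows$overlap == 1 & diag_rows$mcc == 1))
  # panther and sift each miss one (different) variant
  n_ps <- sim$n_common[sim$method_a == "panther" & sim$method_b == "sift"]
  expect_equal(n_ps, 10L)
  # symmetric in overlap
  wide <- tidyr::pivot_wider(sim[, c("method_a", "method_b", "overlap")],
                             names_from = "method_b",
                             values_from = "overlap")
  m <- as.matrix(wide[, -1])
  expect_equal(m, t(m), ignore_attr = TRUE)
})

test_that("UPGMA trees are ultrametric and match the exhaustive-merge oracle", {
  # two leaves: a single cherry with branch lengths d/2
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  tr2 <- upgma_tree(d2)
  expect_equal(sort(tr2$edge.length), c(0.2, 0.2))

  # three leaves: the closest pair is joined first
  d3 <- matrix(c(0, 0.1, 0.8,
                 0.1, 0, 0.9,
                 0.8, 0.9, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- upgma_tree(d3)
  coph3 <- ape::cophenetic.phylo(tr3)
  expect_equal(coph3["a", "b"], 0.1)
  expect_equal(coph3["a", "c"], coph3["b", "c"])

  # random 4-leaf matrices: cophenetic distances equal the oracle's
  set.seed(11)
  for (i in 1:25) {
    d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    d[upper.tri(d)] <- runif(6, 0.05, 1)
    d <- d + t(d)
    tree <- upgma_tree(d)
    coph <- ape::cophenetic.phylo(tree)
    oracle <- upgma_cophenetic_oracle(d)
    expect_equal(coph[letters[1:4], letters[1:4]],
                 oracle[letters[1:4], letters[1:4]], tolerance = 1e-10)
    # ultrametric: all leaves equidistant from the root
    depths <- ape::node.depth.edgelength(tree)[seq_len(4)]
    expect_equal(max(depths) - min(depths), 0, tolerance = 1e-10)
  }

  expect_error(upgma_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("similarity trees serialize to newick", {
  fx <- worked_fixture()
  calls <- binarize_scores(impute_scores(fx$scores))
  sim <- similarity_matrix(calls, fx$scores)
  path <- withr::local_tempfile(fileext = ".nwk")
  tree <- similarity_tree(sim, metric = "overlap", path = path)
  expect_s3_class(tree, "phylo")
  reread <- ape::read.tree(path)
  expect_setequal(reread$tip.label, c("panther", "phdsnp", "sift", "snap"))
})

test_that("histogram overlap is 1 for identical and 0 for disjoint class distributions", {
  profiles <- tibble::tibble(f_wt = c(rep(0.2, 50), rep(0.2, 50)),
                             f_mut = runif(100),
                             ci = c(runif(50, 0, 0.4), runif(50, 0.6, 1)))
  labels <- label_factor(rep(c(TRUE, FALSE), each = 50))
  fd <- feature_distributions(profiles, labels)
  ov <- fd$overlap
  expect_equal(ov$overlap[ov$feature == "f_wt"], 1)
  expect_equal(ov$overlap[ov$feature == "ci"], 0)
  expect_error(
    feature_distributions(profiles, labels,
                          subsets = factor(rep("tie", 100),
                                           levels = c("consensus", "tie"))),
    "empty subset")
})

test_that("class separation in profile features shrinks from consensus to tie", {
  sim <- simulate_dataset(sim_config(n_variants = 1500, seed = 19))
  profiles <- profile_features(sim$variants, sim$alignments)
  strat <- stratify_calls(binarize_scores(impute_scores(sim$scores)))
  fd <- feature_distributions(profiles, sim$variants$label,
                              subsets = strat$subset)
  ov <- fd$overlap
  for (f in c("f_wt", "ci")) {
    o <- ov[ov$feature == f, ]
    expect_lt(o$overlap[o$subset == "consensus"],
              o$overlap[o$subset == "tie"])
  }
})
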
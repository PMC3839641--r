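separable_features <- function(n, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), each = n / 2)
  tibble::tibble(
    panther = ifelse(y, runif(n, 0.8, 1), runif(n, 0, 0.2)),
    phdsnp = ifelse(y, runif(n, 0.8, 1), runif(n, 0, 0.2)),
    sift = ifelse(y, runif(n, 0, 0.01), runif(n, 0.5, 1)),
    snap = ifelse(y, runif(n, 60, 100), runif(n, -100, -60)),
    f_wt = ifelse(y, runif(n, 0.8, 1), runif(n, 0, 0.3)),
    f_mut = ifelse(y, runif(n, 0, 0.1), runif(n, 0.3, 0.8)),
    n_al = sample(20:80, n, replace = TRUE),
    ci = ifelse(y, runif(n, 0.8, 1), runif(n, 0, 0.4)),
    label = label_factor(y))
}

test_that("training on separable classes yields a perfect training-set AUC", {
  feats <- separable_features(200)
  fit <- meta_train(feats, feats$label, model_config(seed = 2))
  p <- predict(fit, feats)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(roc_auc(p, feats$label)$auc, 1)
  # duplicated rows get identical probabilities
  expect_equal(predict(fit, feats[c(1, 1, 7, 7), ]),
               predict(fit, feats[c(1, 1, 7, 7), ]))
  expect_error(meta_train(feats, label_factor(rep(TRUE, 200))),
               "per class")
})

test_that("training is deterministic from the seed and persists to identical predictions", {
  feats <- separable_features(120, seed = 5)
  fit1 <- meta_train(feats, feats$label, model_config(seed = 9))
  fit2 <- meta_train(feats, feats$label, model_config(seed = 9))
  expect_equal(predict(fit1, feats), predict(fit2, feats))
  path <- withr::local_tempfile(fileext = ".rds")
  write_meta_fit(fit1, path)
  reloaded <- read_meta_fit(path)
  expect_equal(predict(reloaded, feats), predict(fit1, feats))
})

test_that("broom tidiers summarise fits and cross-validations", {
  feats <- separable_features(120, seed = 6)
  fit <- meta_train(feats, feats$label, model_config(seed = 1))
  td <- tidy(fit)
  expect_equal(td$feature,
               c("panther", "phdsnp", "sift", "snap", "f_wt", "f_mut",
                 "n_al", "ci"))
  expect_true(all(td$importance >= 0))
  g <- glance(fit)
  expect_equal(g$n, 120L)
  expect_equal(g$n_trees, 100L)

  cv <- meta_cv(feats, feats$label, model_config(n_folds = 4, seed = 1))
  expect_equal(nrow(tidy(cv)), 120)
  expect_equal(glance(cv)$q2, 1)
})

test_that("the decision rule and reliability index have their fixed points", {
  cls <- classify_probability(c(0.5, 1, 0.75, 0, 0.2))
  expect_equal(as.character(cls$call),
               c("polymorphism", "disease", "disease", "polymorphism",
                 "polymorphism"))
  expect_equal(cls$ri, c(0, 10, 5, 10, 6))
  # RI is piecewise linear with fixed points RI(0.5)=0, RI(0)=RI(1)=10
  p <- seq(0, 1, 0.01)
  expect_equal(classify_probability(p)$ri, 20 * abs(p - 0.5))
  expect_error(classify_probability(1.2), "0, 1")
})

test_that("cross-validation predicts every variant exactly once from held-out models", {
  sim <- simulate_dataset(sim_config(n_variants = 300, seed = 13))
  feats <- featurize_dataset(sim)
  cfg <- model_config(n_folds = 6, n_trees = 60, seed = 13)
  cv <- meta_cv(feats, feats$label, cfg)
  preds <- cv$predictions
  expect_equal(nrow(preds), 300)
  expect_true(all(!is.na(preds$p_disease)))
  expect_setequal(preds$protein_id, feats$protein_id)

  # stratification contract: fold sizes differ by at most 1 within class
  for (cls in c("disease", "polymorphism")) {
    sizes <- table(preds$fold[preds$label == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }

  # no leakage: a forest retrained without fold k's variants reproduces
  # exactly the out-of-fold predictions for fold k
  k <- 3
  test_idx <- preds$fold == k
  x <- as.matrix(feats[, c("panther", "phdsnp", "sift", "snap", "f_wt",
                           "f_mut", "n_al", "ci")])
  set.seed(cfg$seed + k)
  forest <- randomForest::randomForest(
    x = x[!test_idx, ], y = preds$label[!test_idx],
    ntree = cfg$n_trees, mtry = cfg$mtry)
  manual <- unname(predict(forest, x[test_idx, ], type = "prob")[, "disease"])
  expect_equal(preds$p_disease[test_idx], manual)

  # the whole run is reproducible bit-for-bit from the seed
  cv2 <- meta_cv(feats, feats$label, cfg)
  expect_identical(cv$predictions, cv2$predictions)

  expect_error(
    meta_cv(feats, feats$label, model_config(n_folds = 200, seed = 1)),
    "folds")
})

test_that("per-protein folds never split a protein across folds", {
  sim <- simulate_dataset(sim_config(n_variants = 120, seed = 17))
  feats <- featurize_dataset(sim)
  # assign 3 variants per pseudo-protein
  protein <- rep(sprintf("G%03d", 1:40), each = 3)
  cv <- meta_cv(feats, feats$label,
                model_config(n_folds = 5, n_trees = 40,
                             fold_scheme = "protein", seed = 2),
                protein = protein)
  spread <- tapply(cv$predictions$fold, protein,
                   function(f) length(unique(f)))
  expect_true(all(spread == 1))
})

test_that("permuted labels give chance-level out-of-fold AUC", {
  sim <- simulate_dataset(sim_config(n_variants = 400, seed = 23))
  feats <- featurize_dataset(sim)
  set.seed(99)
  permuted <- sample(feats$label)
  cv <- meta_cv(feats, permuted, model_config(n_folds = 5, n_trees = 60,
                                              seed = 23))
  auc <- glance(cv)$auc
  expect_lt(abs(auc - 0.5), 0.1)
})

test_that("pushing scores toward their damaging sides raises the mean disease probability", {
  sim <- simulate_dataset(sim_config(n_variants = 500, seed = 31))
  feats <- featurize_dataset(sim)
  fit <- meta_train(feats, feats$label, model_config(seed = 31))
  base <- feats[sample(nrow(feats), 100), ]
  pushed <- dplyr::mutate(base,
                          panther = pmin(panther + 0.3, 1),
                          phdsnp = pmin(phdsnp + 0.3, 1),
                          sift = pmax(sift - 0.3, 0),
                          snap = pmin(snap + 60, 100))
  expect_gt(mean(predict(fit, pushed)), mean(predict(fit, base)))
})

test_that("the reliability trade-off exchanges coverage for accuracy", {
  set.seed(41)
  n <- 1000
  # calibrated predictions: the true class follows the stated probability
  p <- runif(n)
  labels <- label_factor(runif(n) < p)
  preds <- classify_probability(p)
  tr <- reliability_tradeoff(preds, labels)
  expect_equal(nrow(tr), 11)
  expect_equal(tr$fraction_retained[tr$ri_cutoff == 0], 1)
  expect_true(all(diff(tr$fraction_retained) <= 0))
  expect_true(all(diff(tr$q2[!tr$empty]) >= 0))

  # a cutoff above the highest RI present yields a flagged empty row
  low_conf <- classify_probability(runif(50, 0.45, 0.55))
  tr2 <- reliability_tradeoff(low_conf, label_factor(runif(50) > 0.5))
  expect_true(tr2$empty[tr2$ri_cutoff == 10])
  expect_true(is.na(tr2$q2[tr2$ri_cutoff == 10]))
})
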
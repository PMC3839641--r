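---
title: "Methods: ensemble meta-prediction of disease-associated missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble meta-prediction of disease-associated missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`snvmeta` classifies single amino-acid substitutions as disease-associated
or polymorphic by combining the outputs of four established missense
predictors — PANTHER, PhD-SNP, SIFT and SNAP — with evolutionary features of
the mutated site. The working assumption is *method orthogonality*: the
component predictors were built from different models (family HMMs, SVMs on
sequence profiles, PSI-BLAST conservation, neural networks on structural
features) and therefore err on different variants, so a learner over their
joint output can beat the best of them. The package does not re-implement
any component predictor; it consumes their raw scores as data.

Each variant is an 8-element vector: the four raw component scores followed
by F_wt, F_mut (wild-type/mutant residue frequencies in the alignment column
at the mutated site), N_al (non-gap depth of that column) and CI (a
conservation index). A random forest maps the vector to P(D), the
probability of disease association; the call is disease iff P(D) > 0.5, and
each prediction carries a reliability index RI = 20·|P(D) − 0.5| in [0, 10].

Raw scores enter the forest unrescaled — SNAP on [−100, 100] next to
probabilities on [0, 1] — because tree ensembles are invariant to monotone
per-feature scaling; binarized calls are used only for the agreement
stratification and similarity analyses, never as model features.

## Score interpretation and imputation

The method registry (`method_registry()`) fixes the native semantics:

| method  | range        | damaging side | threshold | imputation default |
|---------|--------------|---------------|-----------|--------------------|
| panther | [0, 1]       | > threshold   | 0.5       | 0.5                |
| phdsnp  | [0, 1]       | > threshold   | 0.5       | 0.5                |
| sift    | [0, 1]       | < threshold   | 0.05      | 0.05               |
| snap    | [−100, 100]  | > threshold   | 0         | 0                  |

Two deliberate conventions:

* **Strict inequalities.** A score exactly at its threshold is *neutral*
  for every method. This makes the two conventions compose: a missing score
  is imputed at the threshold, and the imputed value then binarizes to a
  neutral call — an absent prediction never votes for damage.
* **PANTHER polarity.** The damaging side of PANTHER's 0.5 default is not
  fully pinned down by its published description; the shipped registry uses
  "> 0.5 damaging", mirroring PhD-SNP's probability semantics. Polarity is
  registry configuration, so a user with differently oriented PANTHER
  output can flip it (or register further methods with `method_spec()`)
  without touching code.

Imputation (`impute_scores()`) is idempotent and leaves present values
bit-identical; coverage (`score_coverage()`) reports the per-method fraction
of native predictions so that analyses can also be restricted to natively
covered variants.

## Profile features

`column_profile()` computes relative frequencies over the 20 standard amino
acids at one alignment column. Gaps and non-standard codes (X, B, Z) are
excluded from both numerator and denominator; N_al counts the sequences
contributing a standard residue. No pseudocounts and no sequence weighting
are applied — the profile is a plain column count, which keeps the features
exactly reproducible from the alignment and is stated here because profile
pipelines differ on this point.

The conservation index is the normalized-entropy complement
CI = 1 − H/ln 20, with H the Shannon entropy of the 20-state frequency
vector. It is bounded in [0, 1] (1 = invariant column, 0 = uniform column)
and permutation-invariant over residue identities. Other bounded
conservation scores exist; this one was chosen because it is standard,
parameter-free, and matches the [0, 1] axis on which class-conditional
feature distributions are compared. A column with no residues (all gaps)
has undefined frequencies and CI; `site_features()` returns `NA` features
and N_al = 0 for it rather than guessing.

Variant positions are 1-based residue indices into the *ungapped query*
(the first sequence of the alignment) and are mapped to alignment columns
by skipping query gaps. A declared wild type that disagrees with the query
residue is a warning, not an error: real variant tables and alignments
drift out of sync, and the analyst should see the features anyway.

A precomputed profile table (`f_wt`, `f_mut`, `n_al`, `ci` per variant) can
be supplied directly to `build_features()` for pipelines that keep
PSI-BLAST profiles instead of alignments.

## The forest and cross-validation

Defaults in `model_config()`: 100 trees; features per split
mtry = floor(log2(8) + 1) = 4 (the classic WEKA-era rule, recorded
explicitly because R's own default for 8 features would be different);
unlimited depth; no class weighting; decision threshold 0.5. All are
exposed as configuration.

Performance estimates come from k-fold cross-validation (default k = 20)
using *out-of-fold probabilities only* — no refit on the full data enters
any reported metric. Folds are stratified by class at the variant level, so
fold sizes within each class differ by at most one. Fold assignment derives
from the configured seed, and fold i trains with seed `seed + i`, making
the entire run bit-reproducible and every per-fold model independently
reconstructible (the test suite uses this to prove the absence of leakage).
An optional per-protein fold scheme keeps all variants of a protein in one
fold: variant-level folds can leak homology when a protein contributes many
variants, which inflates cross-validated accuracy. The variant-level scheme
remains the default because the reference protocol for this family of
predictors stratifies by variant.

A probability exactly at the 0.5 threshold is called polymorphism (the
"≤ 0.5" side), consistent with the strict-inequality convention for the
component calls. RI is kept continuous; the accuracy/coverage trade-off
(`reliability_tradeoff()`) evaluates the integer cutoffs 0..10, flagging
(rather than erroring on) cutoffs that retain nothing.

## Evaluation metrics

`classification_rates()` applies the standard definitions with disease as
the positive class: Q2 = (TP+TN)/N, PPV, NPV, TPR, TNR. Zero-denominator
rates are `NA` — undefined, deliberately distinct from 0. The Matthews
coefficient uses the usual product-form denominator with the convention
MCC = 0 when any margin is empty. AUC is computed by the midrank
(concordance) formulation, P(s⁺ > s⁻) + ½P(s⁺ = s⁻), which is identical to
the trapezoidal area under the tie-aware threshold sweep; the convention is
stated because naive threshold-sweep implementations disagree on tied
scores. Values are kept at full precision internally; `format_report()`
rounds to the conventional two decimals for presentation.

Pairwise method similarity uses prediction overlap and the MCC of the 2×2
agreement table, computed by default on the variants natively predicted by
both methods of a pair. UPGMA trees over 1 − overlap (or (1 − MCC)/2) are
built by average-linkage agglomeration and serialized as Newick;
ultrametricity is a tested invariant.

The consensus/majority/tie stratification classifies each variant by the
split of its four binary calls (4–0, 3–1, 2–2). Imputed calls participate
by default — they are neutral by construction, and this lets 100% of a
dataset be stratified even when some methods cover only part of it —
with `drop_imputed = TRUE` available as a sensitivity analysis, since it is
genuinely ambiguous whether agreement should be judged before or after
imputation.

## The synthetic generator

`simulate_dataset()` emulates the joint behaviour of the component
predictors so the full pipeline is testable without running any of them.
Per variant with label y ∈ {disease, polymorphism}:

* **Scores.** A shared latent z ~ N(0,1) plus method noise:
  latent_m = β_m·(±1) + w·z + √(1−w²)·ε_m, pushed through the logistic
  function and mapped monotonically onto each method's native scale with
  p = 0.5 landing exactly on the decision threshold. The shared weight
  w (default 0.5) induces the partial inter-method agreement seen between
  real predictors; β_m are the per-method signal strengths (defaults
  0.65/0.70/0.45/0.60 for panther/phdsnp/sift/snap, chosen once to spread
  the component AUCs over roughly the 0.73–0.84 band reported for the real
  tools on large curated sets). Missingness is Bernoulli per method
  (defaults 26% PANTHER, 8% SIFT, 0 otherwise, matching the reported native
  coverage of those tools).
* **Alignments.** A latent conservation level
  c = plogis(0.9·link·(±1) + 0.8·z + 0.9·ε) drives a Dirichlet-categorical
  residue distribution at the mutated site (wild-type concentration grows
  with c, background and mutant tolerance shrink). Coupling c to the same
  shared latent z that drives the scores reflects the fact that the real
  component methods themselves consume conservation: variants on which the
  methods agree also show the cleanest class separation in the profile
  features, which is what produces the consensus > majority > tie accuracy
  ordering and the widening class-distribution overlap from consensus to
  tie. Within-class noise keeps the class-conditional distributions heavily
  overlapping, as they are in real data. Alignment depth is uniform on
  20–80 sequences with a 10% per-sequence gap rate at the site.

What the generator does *not* emulate: realistic protein sequences (flanks
are fixed), annotation noise in curated databases, shared training data
between components (their correlation here is purely the latent factor),
or position-dependent profile structure. Passing tests therefore show that
the pipeline's machinery is correct and that its qualitative behaviour
matches the published structure of the problem — not that any particular
accuracy level would be attained on real SwissVar data.

## Degenerate inputs and tie-breaks

* Scores at a threshold → neutral; P(D) = 0.5 → polymorphism; both strict
  conventions documented above.
* All-gap columns → `NA` features, N_al = 0; `build_features()` refuses
  incomplete profiles rather than imputing them.
* Empty strata in reports and empty RI cutoffs are flagged rows, not
  errors; an all-zero confusion matrix and a single-class ROC are errors.
* Duplicate variant keys collapse to the first occurrence with a warning;
  rows violating the variant invariants are rejected with a per-row report
  attached to the parsed table.

## Problem sizes

The shipped tests run the generator at 120–2000 variants (2000 for the
ensemble-advantage and subset-ordering checks, five seeds, 20-fold CV) and
verify parsing at the full published dataset scales (35,766 and 972
records) on synthetic stand-in files built at run time. These sizes were
chosen as the smallest at which the stochastic properties under test are
stable across seeds.

## Known limitations

* The package scores variants given component outputs; it cannot produce
  those outputs, and its accuracy on real data is bounded by the user's
  upstream predictors and alignments.
* The conservation index is one defensible choice among several; pipelines
  built on weighted or pseudocounted profiles will produce systematically
  different CI values.
* The forest's probabilities are raw vote fractions; no recalibration is
  applied, so RI is a confidence ordering, not a calibrated probability
  scale.
* Variant-level cross-validation can be optimistic in the presence of many
  variants per protein; use the per-protein fold scheme to quantify that
  effect on your data.
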
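---
title: "Consensus modelling of drug-induced cholestasis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus modelling of drug-induced cholestasis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Drug-induced cholestasis (DIC) — impaired bile formation or flow caused by a
drug — is a major form of drug-induced liver injury and a recurring reason
for late-stage attrition and market withdrawal. Public cholestasis datasets
are small (order 10^3 compounds) and imbalanced, with roughly three to four
non-cholestatic compounds per cholestatic one. cholecon implements a
prediction pipeline built for exactly this setting: binary chemical and
biological fingerprints as features, tree ensembles as base learners,
explicit imbalance handling, and consensus vote rules with a
confidence-band filter on top.

# Fingerprint assembly

Every feature is a 0/1 bit in a compounds-by-features block
(`binary_matrix`), and the blocks are concatenated with block-qualified
feature ids before modelling:

* **Targets.** Bioactivity records (compound, target, pChEMBL, assay type)
  are collapsed per pair by the *maximum* pChEMBL value — the most potent
  measurement wins — and binarized at pChEMBL >= 5, i.e. activity at 10 uM
  or better. The comparison is inclusive because the activity definition is
  "at least" this potency. Max aggregation makes the operation invariant to
  record order and duplication, which the tests assert.
* **Predicted targets.** Predictions from external target-prediction tools
  are consumed as additional binary target matrices and merged with the
  known interactions under a tool-agreement threshold: `min_tools = 1`
  includes every prediction, 2 and 3 require that many tools to agree.
  Known interactions are never subject to the agreement threshold — they
  are experimental evidence, not a fifth "tool".
* **Pathways.** Each compound's active targets are expanded by their
  first-degree protein-protein interaction neighbours, the resulting
  protein set is mapped to pathway annotations, and bits are restricted to
  liver-expressed pathways. Whether the direct targets' own pathway
  assignments count, or only the interactors', is genuinely ambiguous in
  this construction; we include direct-target pathways by default
  (`include_direct = TRUE`) on the reading that the pathway layer describes
  "targets and their interactome", and expose the interactor-only variant
  as an option.
* **Transporters.** Hepatic transporter inhibition (BCRP, BSEP, MATE1,
  MDR1, MRP3, OATP1B1, OATP1B3, OCT1, OCT2) enters as one bit per
  transporter: a compound is an inhibitor when at least 3 of the
  per-algorithm binary predictions agree (5 algorithms per transporter, 4
  for OATP1B1). The rule is applied uniformly to 4- and 5-vote lists.
* **Substructures.** Precomputed structural keys (e.g. 881-bit
  PubChem-style fingerprints) are read as a ready-made block; the key
  definitions themselves are out of scope.

Compounds whose row is duplicated within the target, pathway, or
substructure space (`unique_across()`) are dropped before modelling: a
duplicate in any one space disqualifies, and the nine transporter bits are
too short a fingerprint to justify the test, so they are never consulted.
`coverage()` reports set-bit density as a fraction; percent formatting is a
reporting-layer concern (`format_percent()`).

# Imbalance handling

Two balancing procedures are implemented, both applied to training data
only (including inside every cross-validation fold):

* **SMOTE** grows the minority class to the majority size by interpolating
  between a minority compound and one of its k = 5 nearest minority
  neighbours under Euclidean distance. Synthetic rows are fractional and
  are deliberately *not* rounded back to bits — the tree learners accept
  them, and rounding would collapse distinct interpolants. Originals are
  preserved unchanged.
* **Undersampling (US)** partitions the majority class uniformly at random
  into 4 disjoint near-equal subsets and pairs each with the full minority
  class. With a 550/169 training composition this yields subsets of
  137-138 majority compounds, so the per-subset imbalance inverts slightly
  (169 minority vs ~137 majority); no correction is applied — the
  consensus vote absorbs it.

The train/test split is stratified: total training size is
`floor(0.8 * N)` and per-class counts follow largest-remainder
apportionment of the class quotas, the only rounding rule that keeps every
class within one compound of its exact quota while hitting the floored
total exactly. Remainder ties go to the larger class.

# Consensus rules

* **US consensus (4 submodels).** Each submodel votes at the 0.5
  probability cut (0.5 itself is a positive call). Three or four votes:
  active. Zero or one: inactive. Exactly two: the mean of the four
  probabilities decides at 0.5. The mean probability is always stored
  because the confidence filter operates on it.
* **Expanded consensus (9 members).** Four US gradient-boosting submodels,
  four US random-forest submodels (sharing one majority partition by
  default, configurable), and one SMOTE-trained single model — the better
  of the GB and RF SMOTE candidates by pooled cross-validated balanced
  accuracy. An odd member count avoids ties; a compound is active iff at
  least 5 of 9 members vote active.
* **Probability-range filter.** Compounds with mean probability in
  [0.35, 0.65] — boundaries inclusive — are set aside as too uncertain to
  call. Retained labels are re-derived from the mean probability alone
  (below 0.35 inactive, above 0.65 active), which makes the filtered
  confusion matrix an exact function of the three-band count table
  (`metrics_from_bands()`): low-band positives are false negatives,
  high-band negatives false positives, and so on.

The band semantics `[0, 0.35) / [0.35, 0.65] / (0.65, 1]` and the
band-to-label mapping were chosen together so that filtered metrics,
band tables, and exclusion summaries are mutually consistent — the test
suite checks the identity `metrics_from_bands(band_table(p, y)) ==
compute_metrics(confusion(...))` on the retained subset for random inputs.

# Evaluation

Metrics come from the standard 2x2 table with cholestasis-positive as the
positive class: accuracy, sensitivity, specificity, precision, MCC, and
balanced accuracy = (sensitivity + specificity)/2. MCC is the headline
robust metric under imbalance; balanced accuracy is the model-selection
criterion (`select_best()`, compared at 3 decimals with ties broken by
sensitivity, then MCC, then name) because it penalises the
high-specificity/low-sensitivity failure mode that imbalanced training
induces. Any metric with a zero denominator is reported as `NA`, never
silently 0 — degenerate folds must be visible.

Cross-validation is stratified k-fold (default 10) with balancing applied
inside each training fold; out-of-fold predictions are *pooled* over all
compounds, so every compound is predicted exactly once and the pooled band
table over a 719-compound training set sums to exactly 719. Pooling, not
fold-averaging, is what makes band-count bookkeeping and metric
recomputation exact.

Feature influence is aggregated across the four US submodels by scaling
each submodel's importance vector to its own maximum (top feature = 1.0),
averaging, and ranking descending (`mean_scaled_importance()`). Per-model
scaling stops any single submodel with large absolute impurity scores from
dominating the mean.

# Base learners and defaults

Random forests use ranger (500 trees, impurity importance) and gradient
boosting uses xgboost through the classic `xgb.train` interface with
50 rounds, depth 5, learning rate 0.1 — conventional GBM-tier settings for
tabular binary data of this size. Both run single-threaded with explicit
seeds, so every fit is reproducible; all seeds are recorded in the
pipeline's provenance record. Hyperparameters are overridable per
`learner_spec()`, and all package defaults are deliberately modest: with
~10^2-10^3 compounds and mostly sparse bits, deeper/longer boosting mainly
buys variance.

# The synthetic generator

`make_binary_dataset()` draws every bit independently Bernoulli with a
class-conditional rate: a few informative features get distinct
positive/negative presence rates, all others a per-block background rate.
The defaults emulate the baseline study conditions at quarter scale — 172
negative / 53 positive compounds (about 3.3:1), block widths 270/512/220/9
with background rates matching the observed per-fingerprint bit densities
(0.9%, 11.4%, 14.5%, 7%), and informative presence-rate pairs 0.69/0.47,
0.55/0.33, 0.40/0.22, 0.21/0.08 as seen among top-ranked real descriptors.
Quarter scale keeps full-pipeline tests in seconds while preserving the
imbalance and sparsity structure.

The calibration experiments in the acceptance script use a deliberately
plain configuration — n = 500 at 3:1 imbalance, one 100-bit block,
background rate 0.2 — so that the null (no informative features) and
planted-signal (five features at rates 0.6 vs 0.2, a 0.4 gap) conditions
differ in exactly one respect. Null data bounds the pooled CV MCC near
zero; planted data must push pooled sensitivity well above chance; and the
probability filter must not cost retained-set sensitivity across seeded
replicates. The filter comparison is made on pooled CV predictions rather
than the 100-compound holdout because a ~25-positive test set quantises
sensitivity in steps of 0.04, swamping the effect being measured.

What the generator does *not* emulate: feature correlation (real pathway
bits are strongly nested by construction), chemistry (no valid SMILES, no
real substructure co-occurrence), or label noise. Passing the synthetic
suite therefore demonstrates that the machinery is correct and calibrated,
not that any particular real-data performance level will be reached.

# Degenerate inputs and numerical corners

* Empty tissue filters yield a 0-column matrix with a warning;
  `coverage()` refuses degenerate matrices outright.
* SMOTE requires minority > k neighbours and errors with advice otherwise;
  an already balanced dataset passes through unchanged.
* Band boundaries are closed into the middle band on both sides; the
  degenerate filter `low = high` is rejected.
* Undefined ratios (no positives among excluded compounds) and undefined
  metrics surface as `NA` with the "undefined" formatting downstream.
* All randomised operations take explicit integer seeds; derived sub-seeds
  are drawn from a seeded stream and stay within 32-bit range.

# Known limitations

* No probability calibration, stacking, or applicability-domain modelling
  beyond the probability band.
* The external target-prediction tools and the transporter base models are
  consumed as prediction files; the package does not reproduce them.
* The pipeline assumes standardized compound identifiers; no chemical
  normalisation is performed.
* Problem sizes in the test suite and acceptance script (quarter-scale
  fixtures, n = 500 calibration sets, 10-fold CV) were chosen so the full
  synthetic programme completes in minutes on one CPU core; they are study
  -scale choices, not statistical optima.
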
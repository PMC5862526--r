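---
title: "Decoding recent experience from immediate-early gene induction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding recent experience from immediate-early gene induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iegdecoder)
```

## The scientific problem

Salient experiences — a drug exposure, a foot shock, reinstatement of
feeding — trigger rapid transcription of immediate-early genes (IEGs such as
*Arc*, *Fos*, *Egr2*) in the brain structures recruited by the experience.
If the combination of *which* genes are induced and *where* constitutes a
reproducible signature, then the identity of an animal's recent experience
should be decodable from a handful of qPCR measurements. `iegdecoder`
implements that decoding analysis end to end: ΔΔCt normalization of raw
cycle-threshold (Ct) tables, marker-gene ranking, a leave-one-out
nearest-neighbor decoder, label-permutation validation, and three
feature-selection procedures. A synthetic-data module generates inputs with
the statistical structure the analysis assumes, so every stage is testable
without laboratory data.

## From Ct to features

qPCR reports a Ct value per (animal, structure, gene): the PCR cycle at
which the amplification signal crosses threshold. Ct is logarithmic in
transcript abundance; assuming 100% primer efficiency, one cycle is exactly
one doubling, so all arithmetic below is base 2.

1. **Global reference.** For each sample (one animal × structure
   dissection), the arithmetic mean Ct of a set of stably expressed
   reference genes (defaults: *Dkk3, Tagln3, Gars, Scrn1, Rpl36al, Mcfd2,
   Psma7, Hpcla4*) defines a per-sample normalization value. Averaging
   several reference genes avoids propagating a single housekeeping gene's
   measurement error into every ratio; `delta_ct(mode = "single_gene")`
   provides the classical GAPDH-style alternative.
2. **ΔCt.** `dct = ct(gene) − ref_ct(sample)` removes per-sample input
   differences: any constant Ct shift of a sample (more or less RNA loaded)
   cancels exactly, a property the test suite asserts.
3. **ΔΔCt fold induction.** Each sample's ΔCt is referenced to the *mean*
   ΔCt of its matched control group and converted to a linear ratio,
   `fold = 2^−(dct − mean(dct_controls))`. Averaging controls on the ΔCt
   (log) scale makes the reference a geometric mean of expression, so the
   folds of a control group's own members always have geometric mean 1 —
   an invariant checked on every simulated dataset. Averaging the controls'
   linear folds instead would bias the reference upward under noise; the
   log-scale reading is the default and the one we consider correct.
4. **Feature assembly.** One row per animal, one column per
   (gene, structure) pair; the default panel is 5 IEGs × 5 structures
   (limbic cortex, nucleus accumbens, dorsal striatum, amygdala, lateral
   hypothalamus) = 25 features. Animals missing a feature are dropped by
   default (`missing_policy = "drop"`); imputation at fold 1 is available
   but off, because an imputed "no induction" is indistinguishable from a
   measured one downstream.

**Feature scale.** Published accounts of this analysis do not state whether
the decoder consumed linear or log2 fold values. We default to log2: it
symmetrizes induction and repression, matches the scale on which the noise
is approximately Gaussian, and keeps single large inductions from dominating
Euclidean distances. Both scales are first-class
(`assemble_features(transform =)`, `set_transform()`), and the reproduction
test tries both and identifies the matching one empirically.

## Marker ranking

Candidate genes are ranked by two criteria computed on the fold table:

- **Frequency of induction** `induction_frequency()`: the number of
  (structure, experience) cells whose group-mean fold reaches 2 (inclusive
  `>=` by default; a strict flag exists), out of
  `n_structures × n_experiences` cells.
- **Average variance of induction** `induction_variance()`: by default the
  variance across replicate animals within each cell, averaged over cells,
  on the linear fold scale. The alternative reading — variance of the cell
  means across cells — is selectable (`cells = "across"`); the definition
  behind published S² values is ambiguous, so the reproduction test checks
  which of the two reproduces them.

`rank_markers()` combines the two by rank sum (frequency descending,
variance ascending), ties broken alphabetically — the minimal reading of
"combined highest ranking".

## The decoder

`loo_evaluate()` scores a 1-nearest-neighbor classifier (Euclidean metric,
`k` configurable) by leave-one-out: each animal is classified from all
others. No feature standardization is applied before the distance
computation (none is described for the original analysis); distance ties are
broken toward the lowest row index and majority ties toward the nearest
member, making every result deterministic. `collapse_features()` probes
where the signal lives: per-gene sub-matrices (spatial pattern of one gene),
per-structure sub-matrices (gene panel in one region), or per-gene means
across structures (spatial information discarded).

## Permutation validation

`permutation_test()` rebuilds the LOO accuracy on `N` label-shuffled copies
and reports the empirical p-value with the strict inequality,
`p = (1/N) Σ 1[acc(S_i) > acc(S)]`, which can legitimately be 0; the
add-one estimate `(r+1)/(N+1)` is attached as `p_add_one` for reporting.
Because permuting labels changes no distance, the neighbor ranking is
computed once and each shuffle costs O(n) — the study-scale `N = 1e5` runs
in seconds. When `n! ≤ N` the permutation group is enumerated exhaustively
instead of sampled. Shuffles are unconstrained uniform permutations
(fixed-point-free "derangement" sampling is deliberately not used; the
identity permutation is a legitimate, measure-1/n! member of the null).

A note on calibration: the empirical p is a discrete statistic, so under a
true null it is uniform only up to tie mass. The test suite checks
calibration with the tie-randomized probability integral transform, the
standard device for discrete p-values, and separately asserts the strict p
is not anticonservative.

## Feature selection

- **Random-KNN support** `rknn_support()`: sample feature subsets (sizes
  uniform on 1..25, members uniform without replacement), score each by its
  LOO accuracy, and define a feature's *support* as the mean accuracy of
  the sampled classifiers containing it. Exhaustive enumeration replaces
  sampling on request for small panels, which is how the test suite pins
  the estimator to a brute-force oracle.
- **Random-forest MDG** `rf_importance()`: Gini trees grown to purity on
  bootstrap samples, each on a random feature subset of varying size
  (1..25) — per-tree subsets rather than the per-split `mtry` of standard
  random forests, which is why the ensemble is implemented here rather than
  delegated; the standard implementation serves as a ranking cross-check in
  the tests. "Mean decrease in Gini" is the node-fraction-weighted impurity
  decrease summed within a tree and averaged over the trees containing the
  feature. Where the original description says "modified" Gini gain without
  defining the modification, we implement the standard size-weighted
  decrease and record the ambiguity here.
- **Pruned-tree evaluation** `evaluate_pruned_tree()`: a feature subset is
  scored by stratified 10-fold cross-validation of a Gini CART limited to
  depth 4 with at least 3 animals per leaf.
- **Descriptive tree** `build_cart_tree()`: an unconstrained CART grown to
  purity with information-gain (entropy, bits) splits, thresholds at
  midpoints of consecutive sorted values, ties to the lower feature index
  then lower threshold; rendered as indented text plus a node table.

Ensemble sizes: the study-scale values are 1e6 subsets / 1e5 trees; package
defaults are 1e4 / 1e3, which reproduce stable top-of-ranking behavior at
25 features (Kendall τ ≥ 0.8 across seeds in our acceptance checks) at
interactive cost. Pass larger values for publication-grade runs.

## The synthetic-data generator

`sim_config()` + `generate_feature_matrix()` / `generate_ct_dataset()`
emulate the study design with known ground truth. Defaults, chosen once to
mirror the study conditions: 10 experience classes, 5 genes × 5 structures,
5 mice per class (a vector of per-class counts is accepted, e.g. to hit the
study's 54 animals), class signatures of 8 features induced at a mean of 3
log2 units, within-class SD 0.5 log2 units, technical Ct noise 0.25 cycles,
baseline Ct 24 (markers) / 20 (reference genes). Effects are Gaussian on
the log2 fold scale — equivalently Gaussian on Ct, the scale on which qPCR
error is approximately normal — and one configured log2 unit appears as
exactly one cycle of Ct decrease in treated animals. Control groups are
generated per experience with the same n as treated animals, at timepoint
0 hr.

Two signature regimes are used deliberately:

- the **diffuse default** (signatures drawn from all 25 features) makes
  nearly every feature informative for some class — the right condition for
  decoding, permutation and normalization checks;
- a **structured mask** (`signature_effects(feature_pool =, distinct =
  TRUE)`; e.g. 7 informative features, distinct 4-feature signatures) gives
  feature selection a true hierarchy to recover. Ranking *stability* and
  mask-recovery statistics are only meaningful in this regime: when all
  features are near-exchangeable, the identity of the "top 5" is sampling
  noise by construction.

What the generator does **not** emulate: induction time courses (the 0/1/2/4
hr dynamics; all treated animals sit at the 1 hr peak), habituation
trajectories across days, cell-type heterogeneity within a dissected
structure, correlated noise between genes in a sample beyond the shared
loading shift (`sample_shift_sd`, default 0), and class-dependent variance.
Passing tests on these simulations therefore demonstrate the correctness of
the computations and the internal consistency of the pipeline, not that
real brain data meet the model's assumptions.

## Numerical and design choices

- Within-group variances for the generator are not published for the
  original dataset; 0.5 log2 units within class was chosen once as a
  realistic qPCR biological spread and is the value under which all
  calibration statements hold.
- The fold-table geometric-mean invariant is asserted to 1e-10; ΔΔCt
  round-trips are exact to double precision.
- Problem sizes in the test suite: property checks run at n ≤ 30 with
  brute-force oracles; calibration uses 200 replicates × N = 200
  permutations; recovery uses 50 seeded replicates at the study conditions
  (effect 3, noise 0.5, n = 5/class); ensemble checks run 1e4 subsets and
  1e3 trees at 54 × 25, three seeds each. These sizes were chosen as the
  smallest at which the statistics being asserted are stable.
- `k = 1` is the decoder default throughout; majority voting only engages
  for `k > 1`.

## Known limitations

- The reproduction of the published accuracies requires the study's
  deposited expression tables, which are not redistributable with the
  package; the reproduction test documents the drop-in format and runs
  whenever the file is present.
- Primer efficiency is assumed to be exactly 2 per cycle; no
  amplification-curve or batch-effect correction is provided.
- The pruned-tree cross-validation accuracy depends strongly on whether the
  feature subset contains single features that split several classes at
  once; on diffuse synthetic signatures it sits well below the k-NN
  accuracy, which is expected (axis-aligned depth-4 splits are a much
  weaker hypothesis class than 1-NN in 25 dimensions).

## A worked run

```{r example, eval = FALSE}
report <- run_pipeline(list(
  seed = 1,
  simulate = list(n_per_class = 5),
  n_permutations = 1000,
  n_subsets = 2000
), out_dir = "ieg_run")

report$confusion          # LOO confusion matrix and accuracy
report$permutation        # empirical p against the shuffled-label null
head(report$selection)    # Random-KNN support ranking
print(report$tree)        # descriptive information-gain tree
```
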
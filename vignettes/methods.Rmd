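---
title: "Methods: similarity networking, conformal prediction and recall-calibrated prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity networking, conformal prediction and recall-calibrated prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the parameters that matter, the
numerical conventions adopted where the methods literature leaves a
choice open, and what the synthetic test bed does and does not
demonstrate.

## The screening problem

Non-targeted LC/HRMS screening yields thousands of features, each at
best accompanied by an MS² fragment spectrum. Only a tiny fraction can
be structurally identified, so toxicity-oriented screening needs a
*prioritization* step: estimate, from the spectrum alone, whether a
feature is likely to act on an endocrine endpoint (AhR, AR, ER and
related nuclear-receptor assays), and spend identification effort on the
flagged features. All three frameworks in this package share one working
assumption — that spectral similarity carries information about
structural similarity, which in turn carries information about shared
bioactivity. Both links are noisy and the second is the weaker one:
endocrine disruption spans many unrelated scaffolds, which is precisely
why the package also carries the evaluation machinery to quantify how
far similarity alone gets.

## Spectral similarity

Two fragment peaks match when their m/z values differ by at most the
tolerance (`mzTolerance`, default **0.2 Da**, the conventional value for
unit-resolution peak matching in spectral networking). The greedy cosine
ranks all candidate peak pairs by descending intensity product — ties
broken by ascending m/z in the first, then the second spectrum, making
the score bit-reproducible — and accepts pairs greedily with each peak
used at most once; the matched intensity-product sum is divided by the
product of the two intensity-vector norms, so scores live in [0, 1] and
do not depend on intensity scale. The modified cosine additionally
admits pairs offset by the precursor-mass difference of the two spectra,
so a fragment shifted by a single structural modification still matches;
it therefore requires both precursor m/z values and refuses spectra
without one.

Two deliberate conventions: tolerance comparisons are *inclusive*
(`|Δm/z| ≤ tol`), and intensities enter *unweighted* (no square-root or
m/z weighting) — both are configurable facts of this implementation
rather than claims about the one true cosine. Greedy matching can be
suboptimal when candidate pairs conflict; the test suite checks it
against an exhaustive optimal-assignment oracle on small spectra (never
exceeding it, and equal when candidates do not conflict).

Learned spectral similarities (e.g. from a Siamese-network scorer
trained to predict structural similarity) enter only as a precomputed
matrix through `loadExternalMatrix()`, which enforces symmetry (within
1e-6), the [0, 1] range and id coverage. Fingerprint networking uses
Tanimoto similarity, |a ∧ b| / |a ∨ b|.

## Activity networking and voting

`buildNetwork()` connects labeled compounds whose similarity reaches the
threshold; compounds with inconclusive assay labels are removed *before*
construction, so they neither vote nor receive votes. Thresholds are
conventionally scanned from 0.0 to 0.9 in 0.1 steps. The optional
edge-filtering step keeps, per node, only the `topK` (conventionally 6)
most similar passing neighbors; an edge survives when **either** endpoint
ranks the other in its top k. This union rule is a design decision — the
"k most similar per node" phrasing common in the field does not say
whether one or both endpoints must agree — chosen because it preserves
the symmetry of the underlying similarity. Ties at the k-th rank break
by ascending compound id. Filtering is applied after thresholding.

Voting follows the two schemes given in the README; an isolated node
receives no probability and is reported `connected = FALSE` rather than
being silently scored 0 — the distinction matters for every metric
below. Leave-one-out evaluation builds the topology once and predicts
each node from its neighbors' true labels; since there are no
self-edges, a node's own label never reaches its own prediction.

## Modified ROC metrics

Raising the similarity threshold disconnects nodes, and a classical ROC
analysis computed only on connected nodes would reward exactly that.
The modified rates keep every labeled compound in the denominators:

mTPR = TP / (TP + FN + NCP),  mFPR = FP / (FP + TN + NCN),

with NCP/NCN the unconnected actives/inactives. Three integration
conventions had to be fixed because the bare definitions do not
determine them:

* decision thresholds sweep the set of observed probabilities plus one
  value above the maximum; classification at a threshold is inclusive
  (`p ≥ t`);
* the curve is anchored at (0, 0) and extended *horizontally* from its
  terminal point to mFPR = 1, so all areas share the [0, 1] scale while
  a terminal mTPR below 1 (unconnected actives) permanently caps the
  area — the penalty persists through the integration;
* the area is trapezoidal.

With no unconnected compounds these metrics provably collapse to the
classical ones; the suite verifies agreement with an independent ROC
implementation to 1e-9 on random fixtures.

`fprAtTpr()` — the false positive rate at a fixed recall, the workload
metric used to compare approaches — is deliberately *classical*:
unconnected compounds count as predicted negative at every threshold, so
the metric is comparable across networking (which has a connectivity
notion) and the two supervised approaches (which do not). The attainable
recall is then capped by the connected actives; an unreachable target is
reported as such (`reachable = FALSE`) with the point of maximal recall,
never silently substituted. The returned threshold is the largest one
whose recall reaches the target, which is also the one with the lowest
false positive rate among those that do.

## Mondrian inductive conformal prediction

Compounds are featurized as their similarity to every member of a fixed
training panel (`similarityFeatures()`). `fitICP()` splits the training
data into a proper-training part and a calibration part (stratified,
`calibrationFraction` default 0.2), fits the base classifier on the
proper part only, and stores per-class calibration nonconformity scores
α = 1 − P̂(true class). The p-value of class c for a query is
`(#{α_cal,c ≥ α_x} + 1) / (n_c + 1)` — the +1-smoothed, non-randomized
variant, with ties counting toward the numerator; both choices are
conservative and keep the procedure deterministic. Prediction sets
contain every class whose p-value exceeds ε; per-class validity (error
rate at most ε for each class separately) holds under exchangeability of
calibration and test examples regardless of how good the base model is,
while *efficiency* — the fraction of single-label sets — is what a good
base model buys. The conventional significance grid is
ε ∈ {0.15, 0.20, 0.25, 0.30}.

The base learner is pluggable behind a `fit`/`predictProb` contract. The
default is a bagged-tree ensemble (`randomForestLearner()`, with an
optional active-class weight for imbalanced assays). The replicated
validity study in the test suite uses the gradient-boosted learner
(`xgboostLearner()`) instead: validity is learner-agnostic, and the
boosted learner fits the 1000-feature design in a fraction of the time,
which is what makes 200 replicates practical. One subtlety in the study
design: the similarity-feature panel is the proper-training set only and
is disjoint from calibration and test rows. If calibration compounds
also anchored the features, each calibration row would carry a
self-similarity of 1.0 that no test row can have — a small but
systematic exchangeability violation.

## Fingerprint classifier

`cleanFeatures()` removes, in order: constant bits; near-zero-variance
bits (most-common/second-most-common frequency ratio above 19 — i.e.
95/5 — while distinct values are under 10% of rows, the caret
convention, since the thresholds are rarely reported in applications);
then highly correlated bit pairs (|Pearson r| ≥ 0.9), resolved
iteratively from the highest correlation down, dropping from each pair
the bit with the larger mean absolute correlation to the remaining bits
(ties drop the later bit name). The procedure is idempotent and the
report partitions the original bits exactly.

`trainClassifier()` runs a randomized search (default 20 trials here;
large studies conventionally use 500) over a declared grid — tree depth
2–8, learning rate log-uniform on [0.01, 0.3], 50–300 boosting rounds,
row/column subsampling on [0.5, 1], and a class weight of 1 or the
inactive/active ratio — scored by mean ROC-AUC over stratified CV folds,
then refits the winner on all data. It also returns the winner's
*out-of-fold* predictions: resubstitution probabilities of a boosted
ensemble are saturated and useless for calibrating decision thresholds,
so any threshold-at-recall derivation should use `cvPredictions`, which
is what the prioritization pipeline does.

## Wastewater prioritization

`classifyFate()` uses the effluent/influent intensity ratio r:
persistent when 0.8 ≤ r ≤ 1.2 (change within ±20%), transformation
product when r ≥ 1.5 (at least 50% higher in the effluent), other
otherwise. Boundaries are inclusive, the ratio is taken relative to the
influent, a feature absent from the influent is a transformation
product, and one absent from the effluent is "other" (removed); a
feature absent from both is an error, not a category. Spectrum quality
gating uses `qualityFilter()`: at least five peaks with relative
intensity strictly above 5%.

`prioritizeFeatures()` derives, per approach, the decision threshold
achieving the target recall (default 90%) on that approach's training
evaluation via `fprAtTpr()`, then labels each feature active/inactive —
or *unavailable* when it cannot be scored (no usable spectrum or
fingerprint). `consensus()` tabulates exact agreement subsets UpSet-style
and keeps features with any unavailable prediction in a separate
stratum: treating "could not be scored" as "inactive" would silently
bias the agreement counts.

## The synthetic test bed

`synthConfig()`/`generateCompounds()` draw per-bit Bernoulli
fingerprints in which a small set of hidden toxicophore bits determines
activity (OR over the set, flipped at `labelNoise`); the toxicophore
prevalence is back-computed from the target active fraction (the 3–16%
range typical of nuclear-receptor assay panels, default 16%), and the
draw is repeated if the realized fraction misses the target by more than
5 points. Each set bit emits fixed characteristic fragment peaks (a
deterministic hash of the bit index into 50–500 Da) with Gaussian m/z
jitter plus uniform noise peaks, so spectral similarity genuinely tracks
fingerprint overlap and the strength of that link is tunable. The
`mn-demo` preset uses many sparse background bits (203 bits at 2.5%
prevalence) so that two random compounds rarely share a bit while
compounds sharing a toxicophore always share its peaks — the regime in
which label propagation on a similarity graph is expected to work, and
the test suite verifies that it does (leave-one-out mROC-AUC above 0.8
at low noise, label-permuted baseline at chance). The `cp-validity`
preset (3200 exchangeable compounds: 1000 panel, 200 calibration, 2000
test) and `fp-recovery` (600 compounds, 5% label noise) fix the other
two study conditions; `wastewater` reproduces the 40-persistent /
153-transformation-product strata among 968 features.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: fragmentation chemistry (neutral losses,
rearrangements), isotope patterns and adduct diversity, intensity-
dependent peak detection, correlated assay endpoints, and above all the
real, much weaker coupling between spectral similarity and bioactivity.
Recovery results on synthetic data are a correctness check of the
machinery, not a performance claim.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the
caller's RNG state; generation uses integer-indexed draws only, so
results are platform-stable. The shipped evaluations use 250 compounds
for networking recovery, 600 for classifier recovery, 3200 × 200
replicates for conformal validity, and 968 features for the fate study
— sizes chosen so the full suite runs in minutes on a single core while
keeping binomial noise well inside the asserted margins. The held-out
recall check averages three replicates because a single 150-compound
test set leaves ±5-point binomial noise on a 90% recall estimate.

## Known limitations

* Greedy peak matching is not the optimal assignment; scores can be
  slightly conservative on spectra with dense candidate conflicts.
* The mROC integration convention (horizontal terminal extension) is one
  of several defensible choices; areas from other conventions differ in
  the third decimal when many nodes are unconnected.
* The conformal guarantee is marginal per class, not conditional on any
  feature; and it assumes exchangeability, which re-optimized thresholds
  or covariate shift between library and field spectra will break.
* Label cleaning's any-active rule is deliberately precautionary and
  will inflate the active class where assay replicates disagree.
* MSP/MGF parsing targets the common NIST-style and GNPS-style dialects;
  exotic vendor variants may need pre-conversion.
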
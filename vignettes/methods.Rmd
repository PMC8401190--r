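---
title: "Inferring synthetic-lethal gene pairs from CRISPR dependency screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring synthetic-lethal gene pairs from CRISPR dependency screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Two genes are synthetic-lethal (SL) when a cell tolerates the loss of
either one but not of both. In cancer cells one partner is often already
deficient — mutated or transcriptionally silenced — so knocking out the
other kills the tumor cell selectively. Genome-wide CRISPR knockout
screens across hundreds of cancer cell lines measure, for every gene, a
*dependency score* per cell line (a CERES-style gene effect: more negative
= more required). If knocking out gene *T* hurts specifically the lines in
which gene *F* is deficient, the pair *F → T* is an SL candidate: *F*'s
deficiency creates a vulnerability on *T*.

`slforest` reconstructs this inference as a pipeline: for each target gene
*T* it models the vector of dependency scores across cell lines (the
response) from two predictor cohorts — binary pathogenic-mutation status
and log2(TPM+1) expression of all candidate partner genes — using
all-relevant random-forest feature selection, then turns the selected
(feature, target) pairs into a directed vulnerability network.

## The model and its stages

### Pathogenic-mutation coding

A variant call is pathogenic when its coding score (a FATHMM-style
prediction in [0, 1]) is **strictly greater than 0.7**, or it is annotated
as damaging, or it is a TCGA hotspot; missing evidence never contributes.
A gene is "mutated" in a cell line (coded 1) iff at least one pathogenic
call exists — multiple calls collapse by OR. Genes without pathogenic
calls stay as all-zero columns until the minimum-mutated-samples filter
(default 1, i.e. only all-zero columns are dropped) removes them before
model fitting, since constant predictors are uninformative to trees.

### All-relevant selection with shadow features

Minimal-optimal selectors (lasso, stepwise) keep one representative of
each correlated group; for SL discovery every informative partner matters,
so an all-relevant strategy is used. Each iteration:

1. every surviving predictor column is copied and row-permuted ("shadow"
   features — random probes with the marginal distribution of a real
   predictor but no association with the response; at least 5 shadows are
   kept, padding small designs with extra permuted copies);
2. a regression random forest is fit to the shadow-extended design and
   per-column importances are extracted;
3. `shadowMax` = the best shadow importance; every undecided real feature
   strictly above it scores a *hit*;
4. under the null a feature beats `shadowMax` with probability 1/2, so its
   hit count is Binomial(trials, 0.5); the Bonferroni-adjusted upper tail
   below α = 0.01 confirms a feature, the lower tail rejects it. Rejected
   features (and their shadows) leave the design; confirmed features stay
   in the model — they keep competing with the shadows so that `shadowMax`
   remains calibrated against real signal — but stop accruing hits and
   trials. The loop ends when nothing is undecided or after `max_iter`
   (default 500) iterations; leftovers are reported Tentative and are
   excluded from downstream pairs by default.

The Bonferroni multiplicity is the number of features at the start of the
run, fixed: conservative and order-independent. A feature's reported
importance is the median over the iterations it participated in — robust
to unstable early iterations.

### Importance metrics

The forest engine is implemented in C++ (no suitable regression-forest
dependency is available in the target environment, and the engine is the
computational core of the method): CART trees with variance impurity on
bootstrap samples, `mtry = ceiling(p/3)` (the regression convention),
minimum splittable node size 2 × 5. Trees are invariant to monotone
transforms of a feature, so continuous columns are rank-transformed once
per forest and split search uses a counting sort over the rank domain;
binary columns use an O(n) two-bucket search.

* **gini** — total decrease in node variance (sum of squared errors)
  attributed to a feature's splits, averaged over trees. Fast but biased
  upward for features offering many split points (continuous expression
  vs. binary mutation).
* **permutation_raw** — mean increase in out-of-bag squared error when the
  feature's values are permuted within the OOB rows; unscaled. Unbiased
  but costlier.
* **gini_corrected** — bias-corrected impurity: the forest is fit on the
  design augmented with a permuted copy of every column, and each
  feature's impurity importance is debiased by subtracting the importance
  of its permuted twin (its expectation under no association). Retains
  most of the impurity metric's speed with the permutation metric's
  calibration; the `test-rf.R` suite verifies that it removes the
  many-split-points gap between continuous and binary noise features.

### Direction, scaling, thresholds

Selected pairs are signed with the Pearson correlation between the feature
column and the dependency score. The SL reading requires deficiency →
dependency: **mutation pairs must correlate positively** (mutated lines
more dependent) and **expression pairs negatively** (low expression, high
dependency). The filter can be bypassed for exploratory use. Self-pairs
are removed.

Importances are min–max scaled to [0, 1] **within each (method, feature
cohort) group** over the whole cohort, so that 1 is the strongest pair of
the group; zero-span groups map to 1. Scaled scores form heavy-tailed
distributions, thresholded by **head/tail-breaks**: recursively split at
the mean, keep recursing into the head while it remains a minority
(|head| / |tail| ≤ 40% in the default, literal mode; the canonical
|head| / |all| formulation ships as a config option since the published
formula deviates from the textbook definition). The last break is the
high-confidence threshold; when a distribution yields no break the
absolute fallbacks 0.4 (expression) and 0.5 (mutation) apply. A pair is
"high-confidence" if it exceeds its group threshold under **any** scoring
method. Targets whose dependency distribution has coefficient of variation
sd/|mean| below 0.3 are uniformly required (pan-essential) and are
excluded from SL prioritization, though they remain as network nodes.

### Network semantics

Edges run from the deficient gene to the dependent target; edge width
weight is |PCC|, node shade value the median dependency; per-node stats
(median, CV, SD, range) accompany the export. Multiple (method, cohort)
evidences for one gene pair stay as parallel edges. Exports are
Cytoscape-compatible edge/node CSVs plus GraphML for lossless round trips.

## The synthetic cohort

`simulate_cohort()` generates the validation world: by default 300 cell
lines, 20 dependency targets, 20 mutation features (Bernoulli, frequency
0.15), 20 expression features (Gaussian, gene-level means in [1, 8] and
SDs in [0.5, 1.5], log2(TPM+1)-like), with 5 planted mutation pairs and 5
planted expression pairs at effect size 1.5 (in units of the residual
noise SD, 0.25 — a CERES-like spread around a −0.2 baseline), a 5-feature
collinear expression block (r = 0.7) among the noise features, and 10%
pan-essential genes (mean −1, SD 0.05, CV ≈ 0.05 < 0.3 by construction).
Planted mutation effects raise the dependency score of mutated lines;
planted expression effects enter through a standardized negative loading
(low expression ⇒ high dependency), matching the signs the direction
filter expects. A mutation-call table consistent with the binary matrix
(plus scattered benign calls) allows end-to-end runs through the
pathogenicity filter. Feature counts are desk-scale — real cohorts carry
thousands of features — chosen once so the full validation suite runs on
one CPU in minutes; a green recovery test therefore establishes correct
mechanics and statistical behavior at this scale, not performance on
DepMap-sized data.

## Numerical and design choices

* Strict inequalities throughout where the sources read "higher than":
  the 0.7 coding score, hits vs. `shadowMax`, thresholds vs. scaled
  importance.
* CV uses |mean| because CERES-style effects are predominantly negative.
* Zero-mean dependency columns have undefined CV and are treated as
  non-essential with a warning; constant columns in correlations yield a
  dropped pair with a warning.
* Per-target forest seeds derive from the cohort master seed plus a stable
  polynomial hash of the gene symbol, so cohorts are reproducible and
  order-independent, and targets can be distributed without changing
  results.
* Missing dependency values drop a sample from that target's model only;
  missing predictor cells are median-imputed for the forest but
  correlations use the original values (pairwise complete).
* Config files are YAML with defaults-then-file-then-flags precedence;
  unknown keys are rejected; the effective configuration is echoed next to
  the outputs so any run is reproducible from its output directory alone.

## Known limitations, and one honest red light

**Null control.** The binomial decision rule models hits as fair coin
flips. That null is correct for the *population* hypothesis but not for
the *fixed sample*: among p pure-noise features the empirically
best-correlated one (E[max |r|] ≈ 0.16 at n = 200, p = 20) beats freshly
permuted shadows with probability well above 1/2, so given enough
iterations its hit count crosses the confirmation boundary. A faithful
implementation of the published loop therefore confirms ~1 noise feature
in a substantial fraction of pure-noise datasets; an independent replica
built on a different forest engine (scikit-learn) reproduces the same
behavior, confirming it is a property of the algorithm, not of this
implementation. The acceptance suite asserts the idealized criterion (0
confirmations in ≥95% of seeds) and reports the measured rate; the test is
expected to stay red. In practice the weak false positives carry small
importances and are removed by the scaled-importance thresholds — the
planted-pair recovery runs reach precision ≈ 1 at the high-confidence
threshold.

**Head/tail breaks on small groups.** With only tens of pairs per scoring
group the recursion sometimes places the last break *inside* the cluster
of genuinely strong pairs, yielding a very high threshold and reduced
recall on those seeds; at the published scale (thousands of pairs per
group) the last break isolates a small head instead. The fallback
absolute thresholds bound the damage but cannot remove it.

**Compute scale.** Package defaults keep the published 500-tree/500-
iteration settings; the acceptance tier runs 64-tree forests with the
loop capped at 100 iterations (the customary run count of the reference
implementation) to fit a single-CPU time budget. Statistical parameters
are never scaled down.

**Scope.** The pipeline consumes dependency, expression and mutation-call
tables as given: no CERES computation, no variant-effect prediction, no
copy-number confounder modeling, no live interaction-database queries
(interaction scores join from a user-supplied table), and exact sample-ID
string matching (alias reconciliation is upstream).
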
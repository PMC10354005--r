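---
title: "Multiobjective evolutionary biomarker search with evoboost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiobjective evolutionary biomarker search with evoboost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoboost)
```

## The problem

Biomarker discovery cohorts routinely pair a small number of samples
(tens to a few hundred) with thousands of correlated features and an
imbalanced binary outcome. A single accuracy-maximizing classifier on
such data tends to (a) classify everything as the majority class, and
(b) spread its signal over many redundant features. `evoboost`
addresses both failure modes with a wrapper approach: a niched
multiobjective evolutionary algorithm simultaneously selects a small,
non-redundant feature panel and tunes seven hyperparameters of a
gradient-boosted tree classifier, returning a Pareto front of
low-complexity models rather than a single point estimate.

## The genotype

Each candidate solution is a hybrid chromosome:

* a binary **feature mask** over all p features (initialized with 1–29
  active bits, uniformly placed);
* two **filter genes**: a method gene over {none, ANOVA-F ("kbest"),
  Wilcoxon rank sums, JMI, mRMR} and an integer budget `fs_k`. When a
  filter is chosen, the active set is the intersection of the mask with
  the top-`fs_k` features of that filter's precomputed ranking; an
  empty intersection falls back to the raw mask. The four rankings are
  computed once, before generation zero, so the filters carve
  low-dimensional, statistically grounded subspaces into the search
  landscape;
* seven **hyperparameter genes** of the boosted-tree classifier:
  learning rate [0.01, 0.5], maximum tree depth [1, 10], two pruning
  parameters (minimum split loss [0, 5], minimum child weight [1, 10]),
  two generalization parameters (L2 [0, 10] and L1 [0, 5]
  regularization) and a balancing gene [0.1, 10] that multiplies the
  negatives/positives ratio to give the positive-class weight. This
  concrete assignment of the pruning, generalization and balancing
  roles to booster parameters is the package's declared choice, and the
  bounds are configurable through `hyperparam_bounds()`.

## Scoring a chromosome

Every generation builds one stratified 10-fold cross-validation plan,
seeded with `base_seed + generation`: all solutions of a generation are
scored on the same folds (comparable), while consecutive generations
see fresh splits (no single-split bias). Per fold, the booster trains
with up to 500 rounds, monitored on the validation AUC with a patience
of 50; the retained model is truncated to the best validation
iteration. Training uses exact greedy splits, a single thread and a
fixed seed, so evaluations are bit-reproducible.

Ten objectives, all maximized in [0, 1], are averaged over folds:

* eight classification metrics — accuracy, weighted geometric mean
  (wGM), F1, F2, precision, recall, balanced accuracy, AUC. The wGM is
  `sensitivity^w * specificity^(1-w)` with `w` set to the
  majority-class proportion, so minority-class recall is up-weighted.
  Any ratio with a zero denominator scores 0, the worst value, pushing
  selection away from degenerate confusion matrices;
* two simplicity metrics — feature complexity `1 - n_active/p` and
  split complexity `max(0, 1 - mean_splits/256)`. What matters is their
  direction (simpler models score higher); the linear forms and the
  256-split budget (`s_max`) are the package's declared choices.

The **overall** score is the unweighted mean of the ten; a
**weighted overall** with user weights is also computed. Pooled
out-of-fold predictions are kept to flag *degenerate* models — those
predicting a single class for every sample — which are later excluded
from ensembles.

## Ranking, niching, and the loop

Populations are ranked by fast nondominated sorting on the ten
objectives. Within each front, fitness sharing penalizes crowding: with
the dual distance `d = 0.5 * d_params + 0.5 * d_mask` (normalized mean
absolute difference over the parameter and filter genes; Jaccard
distance between active-bit sets), each solution's niche count is the
sum of the triangular kernel `max(0, 1 - d/0.2)` over its front, and
its niched score is `overall / niche_count`. Two clones therefore halve
each other's scores while a lone solution keeps its own — the mechanism
that prevents premature convergence to a single peak. The equal 0.5
weighting of the two distance parts and the kernel width 0.2
(`sigma_share`) are configurable defaults.

Each generation: binary tournaments on (front, niched score, then a
deterministic chromosome key) pick parents; uniform crossover (per mask
bit and per gene, probability 0.9 per pair) and mutation (bit flips at
`max(1/p, 0.001)`, Gaussian gene perturbations with sd 10% of range at
rate 0.2, clipped to bounds; filter-method resampling at 0.05) produce
offspring; the first front, capped at half the population and thinned
by niched score, passes unchanged. The run stops at the generation
budget or when the best-so-far score has not improved by more than
1e-6 for `stall_generations` generations.

**A note on monotone progress.** Because every generation re-scores all
solutions under a fresh CV plan, the per-generation best fluctuates
even with elitism: an elite that scored well under one split regresses
toward its true performance under the next. This is desirable — it
demotes split-lucky solutions — but it means monotonicity can only be
defined on the *best-so-far* curve, which is what `history$best_so_far`
records and what the stall criterion watches. The per-generation best
is reported alongside it.

## Finalization

After the last generation the final population is re-ranked; the first
front is the result. The solution with the highest overall score is the
best compromise, and its selected feature names form the biosignature.
The front is also combined into two majority-voting ensembles — hard
(label votes, ties broken by the best member's vote) and soft (mean
positive-class probability, threshold 0.5 with ties to the positive
class) — after excluding degenerate members, which reach the front on
simplicity alone and add no discrimination. Surviving members are refit
on the full dataset using the median of their per-fold best iterations
as the boosting budget, since the early-stopping monitor no longer
exists at deployment time; whether to refit or deploy fold models was
an open design point, and refitting was chosen so the deployed model
sees all samples.

## Preprocessing

`preprocess_table()` applies, in order: nominal-to-numeric encoding
(integer codes in sorted lexical order — deterministic, and it keeps p
stable for the mask, unlike one-hot), imputation (default:
class-conditional median with a global-median fallback; mean and
k-nearest-neighbour variants selectable), normalization (default:
min-max to [0, 1], learned once on the full matrix; constant features
map to 0), and merging of duplicate-named features by element-wise
mean. Labels map to {0, 1} with the minority class positive by default.
The chain is idempotent and preserves sample order. Missing markers
recognized: empty string, "NA", "NaN", "nan", "null"
(case-insensitive). Min-max parameters are learned before the
evolutionary run on the full matrix; per-fold renormalization was
considered and not adopted at this scale.

For the information-theoretic filters, continuous features are
discretized into `min(5, ceiling(sqrt(n)))` equal-frequency bins — the
standard plug-in compromise at small n. JMI uses the pairwise joint
form (the sum over selected features s of I((f, s); y)); mRMR uses the
MI-difference criterion. Ties everywhere break to the lowest feature
index so runs are exactly reproducible.

## Synthetic cohorts

`generate_fixture()` builds cohorts with the structure the method
assumes: standard-normal noise features; informative features shifted
by `effect_size` standard deviations in the positive class (a 1-SD
shift gives a single-feature AUC of about Φ(1/√2) ≈ 0.76); redundant
duplicates equal to an informative feature plus noise scaled to a
target correlation; missingness completely at random; ordinal nominal
columns by quartile binning. Two presets emulate the study regimes: an
expression-like cohort (89 samples, 35:54 imbalance, 5 informative
genes plus 10 redundant copies; the feature count is scaled to 2000 so
that full runs complete in minutes on one core) and a
questionnaire-like cohort (631 samples, 50 features, 1:9 imbalance, 6
informative at effect 0.7, 40% ordinal, 5% missing — the effect size is
a declared choice for a "weakly informative" questionnaire item).

What the fixtures do *not* emulate: probe-level microarray noise, batch
structure, informative missingness, or label noise. Passing tests on
these fixtures therefore demonstrate the correctness of the machinery
and the search's ability to enrich planted signal — not field
performance on real cohorts.

## Problem sizes used by the test suite

The suite exercises the full loop at deliberately small scales chosen
so the complete run finishes in minutes on one core: unit fixtures of
40–80 samples with 10–30 features; a determinism/elitism check of two
3-generation runs on the questionnaire preset with population 16; and a
signal-recovery experiment of 20 independent seeds at 80 samples × 500
features (5 informative, effect 1.0, 60:40 classes) with population 20
for 15 generations.

On that recovery experiment, two properties are measured: (i) the final
best solution improves on the generation-0 best — this holds
essentially always, since the search co-tunes hyperparameters and
enriches informative mask bits; and (ii) the final best model's active
set contains at least two of the five planted features. Property (ii)
is demanding at this scale: the population reliably accumulates planted
bits (diagnostic runs show the planted-bit count across masks growing
several-fold over 15 generations), but the single best-overall model is
selected through cross-validation scores whose fold noise at n = 80 is
of the same order as the true gap between one- and two-planted-feature
models, so the winner frequently carries one planted feature plus a
spuriously separating noise feature. A larger generation budget or
population, or repeated-CV scoring, would sharpen (ii) at proportional
cost; the package keeps the stated conditions and reports the measured
rate rather than tuning toward the target.

## Numerical conventions and degenerate inputs

* Features constant within the data score an F statistic of 0; a
  feature separating the classes perfectly is capped at the finite
  sentinel 1e12 rather than infinity.
* Wilcoxon p-values use exact conditional enumeration (valid under
  midrank ties) when the number of group assignments is at most 20 000,
  otherwise a tie-corrected normal approximation with continuity
  correction.
* An empty feature mask is flagged degenerate and scores 0 on all
  classification objectives while keeping its (maximal) simplicity
  scores, so such chromosomes survive only where the front genuinely
  trades performance for simplicity.
* A CV fold whose training split contains one class is skipped and the
  solution flagged accordingly; stratification prevents this whenever
  each class has at least `k` members, which `make_cv_plan()` enforces.
* `fs_k` is interpreted modulo the prescreen list length, so any
  integer gene value decodes validly.

## Known limitations

* Binary outcomes only; multi-class labels are out of scope.
* Filter rankings are computed once on the full dataset before the
  run. This is the method's stated design, but it means the
  cross-validated objective estimates are not fully nested with respect
  to the prescreen; reported CV scores should be read as model-selection
  signals, not unbiased generalization estimates.
* The ensemble pools the dominant front without calibration or
  stacking; pooled probabilities are means, not calibrated risks.
* Batch-effect correction across cohorts is expected upstream.
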
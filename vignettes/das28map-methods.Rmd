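---
title: "Methods: decomposing the DAS28-CRP for psoriatic arthritis with unsupervised maps, generative augmentation and supervised distillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

The DAS28-CRP grades the activity of peripheral arthritis as a weighted sum
of four components — the tender joint count (TJC28) and swollen joint count
(SJC28) over 28 predefined joints, C-reactive protein (CRP, mg/L) and the
patient's global health VAS (GH, 0–100 mm):

$$\mathrm{DAS28\text{-}CRP} = 0.56\sqrt{\mathrm{TJC28}} +
0.28\sqrt{\mathrm{SJC28}} + 0.36\ln(\mathrm{CRP}+1) +
0.014\,\mathrm{GH} + 0.96,$$

with stages remission (< 2.6), low (2.6–3.2), moderate (3.2–5.1, the upper
bound inclusive) and high (> 5.1). Because the composite is a weighted sum,
it implies a logical OR over its components: very different symptom patterns
can produce the same grade. `das28map` asks which of the 58 single items
(28 tender flags, 28 swollen flags, CRP, GH) actually carry the staging
information in a psoriatic arthritis (PsA) cohort, and whether small
subgroups with atypical patterns — outliers — can be characterized at all.

The workflow has four parts: (1) unsupervised structure detection on the
four components — PCA and an emergent self-organizing map (ESOM) with U-,
P- and U\*-matrices; (2) density-guided generative augmentation that
equalizes cluster sizes so small subgroups become learnable; (3) supervised
distillation — random-forest permutation importance with computed ABC (cABC)
categorization under nested Monte-Carlo cross-validation with a
permuted-feature overfitting control; (4) association statistics for
stage/therapy questions. Since comparable patient-level data are
confidential, the package ships a calibrated synthetic cohort generator as a
first-class, tested module; every analysis runs against it.

## The synthetic cohort generator

`cohort_config()` encodes the emulated study conditions: n = 80 patients
whose latent activity class is drawn from a 59/16/5
remission/low/moderate mixture; per-class joint-flag Bernoulli rates,
lognormal CRP and Beta-distributed GH (scaled to 0–100 mm); a planted
"signal joint" — tenderness of the right MCP-2, the metacarpophalangeal
joint of the index finger — whose odds are multiplied by 8 in non-remission
classes; and three injected outlier patients (two swollen-dominant with at
least 6 swollen and at most 1 tender joint, one tender-dominant with the
converse pattern).

Design choices worth spelling out:

* **Stages are emergent.** The generator stores only the latent class it
  sampled; the analysis stage of a patient is always re-derived by scoring
  the generated components through the DAS28-CRP formula. This guarantees
  that staging and components can never disagree. The per-class component
  distributions were calibrated once, by simulation against the formula, so
  that the re-derived stage proportions reproduce the target mixture within
  a few percentage points at n = 1000 (a seeded regression test guards
  this). The calibration is visible in the narrow low-activity CRP spread:
  the low band (2.6–3.2) is only 0.6 score units wide, and because a single
  tender joint moves the score by up to 0.56, no parameterization places
  much more than ~65% of a "low" patient's mass inside the band — the
  spillover is a property of the score's discreteness, not of the
  generator.
* **Joint flags are independent Bernoulli given the class**, except the
  planted signal joint. No joint–joint correlation is modeled: the
  downstream analyses only require a recoverable planted effect, and any
  correlation structure would be invented detail. Consequently the
  generator does not emulate clinically realistic symptom co-occurrence
  (e.g. symmetric involvement), and passing tests say nothing about such
  structure in real data.
* **Lognormal CRP / Beta GH** keep the marginals nonnegative resp. bounded,
  the minimal realism the score's transforms require.

## Unsupervised structure

PCA (`pca_project()`) is the classical eigendecomposition of the
correlation matrix of the z-standardized four components; variable
contributions are squared loadings normalized to 100% per component.

The ESOM (`train_esom()`) is an online self-organizing map on a 50 × 80
toroidal grid — 4,000 neurons, far more than expected clusters, so that
structure can emerge rather than be imposed. Training uses 20 epochs, the
learning rate annealed linearly 0.3 → 0.05 and a Gaussian neighborhood
whose radius shrinks linearly from half the larger grid dimension to 1.
Inputs are the four components rescaled to 0–100 per variable
(`scale_0_100()`); prototypes initialize uniformly in the per-variable data
range; all draws derive from the config seed. Distances are Euclidean
throughout.

Three landscapes summarize the trained map:

* **U-matrix** (`u_matrix()`): per neuron, the mean distance of its
  prototype to its (deduplicated, toroidal) Moore-8 neighbors. Valleys are
  clusters, ridges are boundaries.
* **P-matrix** (`p_matrix()`): per neuron, the number of data points within
  radius r of its prototype — a hypersphere density estimate. The bandwidth
  r is the Pareto radius (`pareto_radius()`): the 20th percentile of the
  nonzero pairwise data distances.
* **U\*-matrix** (`u_star_matrix()`): the U-matrix rescaled by local
  density, `u* = u * (p - max P)/(mean P - max P)` (clipped at 0), so that
  ridges inside dense regions are suppressed and sparse regions amplified.

**Cluster extraction** (`extract_clusters()`) automates what is otherwise a
visual judgement, and several of its defaults were settled empirically on
two-blob benchmark data with known labels:

* Valley floor is the set of neurons at or below the 70th percentile of the
  *occupied* neurons' U\*-heights. A median threshold — the obvious first
  choice — systematically fragments the sparser of two clusters (its
  plateau sits above the median, which is dominated by the denser
  cluster); any threshold between the 60th and 90th percentile recovered
  two planted blobs perfectly, and 70 was fixed as the default.
* Basins are toroidal Moore-8 connected components of the valley floor;
  patients inherit their best-matching unit's (BMU's) basin; off-valley
  neurons join the catchment of the nearest labeled neuron, so basins tile
  the grid.
* **Outliers are "volcanic craters", not just strays.** An isolated
  patient's BMU can never be valley floor: its neighboring prototypes
  interpolate toward the distant bulk of the data, so its U\*-height is
  large. An occupied off-valley neuron therefore forms its own basin only
  if it is both far from any valley neuron (beyond twice the median
  occupied-neighbor spacing, floored at 2 grid units — the radius must
  adapt because a 4,000-neuron map holding 80 patients is sparse
  everywhere) and at a height reaching the 90th percentile of occupied
  heights. Either condition alone fails: unconditional attachment absorbs
  genuine outliers into the nearest cluster, and a fixed small radius
  shatters sparse maps into dozens of spurious singleton groups.
* Basins holding fewer than `min_cluster_size = 3` patients are reported as
  outlier groups, mirroring the 1–2-member outlier "clusters" the analysis
  is designed to surface.

Cluster-vs-stage consistency is tested by Pearson χ² on the cluster × stage
table restricted to clusters with ≥ 5 members (`cluster_stage_association()`);
expected counts in tiny outlier groups would be meaningless.

## Generative augmentation

Subgroups of 1–2 patients cannot be learned from directly, and naive
oversampling with replacement would duplicate identical cases across
training and validation splits. `generate_cases()` instead proposes a seed
patient (uniform over the cluster) plus isotropic Gaussian noise (σ =
half the Pareto radius by default, per dimension on the 0–100 scale),
clips to the observed ranges, and accepts with the P-matrix existence
probability `max(p(BMU), 1)/max(P)` — and only if the candidate's BMU lies
in the seed cluster's basin. Two deliberate choices:

* The existence probability is **Laplace-floored at 1 count**: outlier
  basins can have `p = 0` everywhere (their prototypes may sit farther than
  r from their one or two patients), and an unfloored rule could never
  augment exactly the subgroups the method exists for. The seed case itself
  is the evidence that a point can exist there.
* Generation operates in the **4-component space**, not the 58-item space:
  Gaussian perturbation is meaningless on binary joint flags, and the
  subgroup characterization downstream uses the four components.

`equalize_clusters()` raises every cluster and outlier group to the size of
the largest cluster (`plan_additions()` is the arithmetic), flagging
generated rows `is_synthetic`. With σ → 0 generation degenerates to seed
resampling; a property test pins this limit, and others check that ≥ 95% of
generated cases have their nearest original neighbor in the seed cluster
and that generated-case density tracks the P-matrix.

## Supervised distillation

The binary target is remission vs active (low + moderate merged): moderate
cases are too few to model separately. The protocol
(`cv_scheme()`) reserves a class-proportional 1/3 validation holdout that
feature selection and tuning never touch. On the 2/3 pool, a random forest
(`ranger`) is tuned by seeded uniform random search (trees, mtry, node
size, depth) with stratified 5-fold balanced accuracy — random search
replaces heavyweight Bayesian tuners; the budget is configurable (the
reference protocol's 200 iterations are reachable; the analysis scripts use
5, which on these data changes the selected sets marginally and the runtime
by an order of magnitude). Permutation importance (`permutation_importance()`)
is the mean drop in balanced accuracy over 50 independent shuffles per
feature, computed on the training pool; balanced accuracy is used for
consistency with the evaluation metric. Negative importances are clipped to
0 before categorization, which requires positive data.

`cabc()` implements computed ABC analysis: items sorted descending, the ABC
curve plots cumulative value fraction against cumulative item fraction; the
A|B boundary is the curve point closest to the ideal (0, 1), and the B|C
boundary the last item before the marginal segment slope drops below 1
(the break-even point; the strict inequality matters — on an all-equal
input the slope is identically 1 and the whole set remains in A ∪ B, with
the closest-to-ideal point at half the items). Set A is the "important
few" — the reduced feature set.

`nested_cv_evaluate()` runs 4 outer × 25 inner = 100 runs: each outer
repeat redraws the holdout split; each inner repeat resamples 80% of the
pool (stratified), re-tunes, refits, and scores balanced accuracy and
rank-based ROC-AUC on a fresh stratified 80% subsample of the untouched
validation set. Reported are medians and nonparametric 95% intervals
(2.5th–97.5th percentiles). The **overfitting control** refits after
independently shuffling every selected training feature column: a sound
pipeline must then perform at chance — median balanced accuracy near 0.5
with the interval covering 0.5 — because shuffling severs every
feature–label link while preserving the marginals.

`cluster_membership_importance()` applies the same machinery one-vs-rest
per (equalized) cluster on the four components, reporting each cluster's
most characteristic component and its single-feature performance.

## Numerical conventions and degenerate inputs

* BMU ties break to the lowest row-major (0-based) neuron index; quantiles
  are type-7 (linear interpolation) throughout; quartile labels share the
  lower bin on ties; χ² without continuity correction; Kruskal–Wallis with
  tie correction, H = 0 by convention (with a warning) when all
  observations are identical.
* Constant columns: an error in PCA (no z-score exists); mapped to 0 by
  `scale_0_100()`.
* Uniform P-matrix density makes the U\* rescaling undefined; the U-matrix
  is returned unchanged with a warning.
* `pareto_radius()` refuses all-identical data (no nonzero distance).
* Augmentation failing to accept within `max_attempts_per_case × n` raises
  an error reporting the achieved acceptance rate rather than looping
  forever.

## Problem sizes used in tests and scripts

The shipped tests and analysis scripts run the complete protocol at sizes
chosen to exercise every code path on a single CPU in minutes: synthetic
cohorts of n = 80–200, two-blob benchmarks of 80–120 points on 20 × 30
maps (the default 50 × 80 map is used where the map itself is under test),
tuning budgets of 3–5 random draws, and the full 4 × 25 = 100
cross-validation runs. The permuted-control and planted-signal checks —
the two headline properties — use n = 200 cohorts, 50-shuffle importances
and all 100 runs.

## Limitations

* The generator's independence assumptions (no joint–joint correlation, no
  demographics, single visit) mean recovery results certify the algorithmic
  pipeline, not clinical validity on real cohorts.
* Cluster extraction automates a judgement the original methodology made
  visually; its thresholds are documented, configurable surrogates, and on
  data without clear valley/ridge structure the partition is sensitive to
  them.
* With ~80 patients on 4,000 neurons every map is sparse; outlier detection
  then rests on the crater heuristic described above, which can both miss
  borderline outliers and flag extreme-but-ordinary patients.
* The 58-item representation treats CRP and GH on their raw scales next to
  binary flags; random forests tolerate this, but importance comparisons
  across scale types inherit the forest's split biases.
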
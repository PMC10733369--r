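# das28map

Machine-learning re-evaluation of the DAS28-CRP composite score for
psoriatic arthritis (PsA): which of the score's 58 individual items —
28 tender-joint flags, 28 swollen-joint flags, C-reactive protein, and the
patient global health VAS — actually carry the information about disease
activity, and can small outlier subgroups be characterized at all?

The package is aimed at biostatisticians and rheumatology researchers who
want to decompose composite clinical scores. It implements, as tested
reusable functions plus a numbered analysis workflow:

* **Scoring & staging** — DAS28-CRP
  (`0.56√TJC28 + 0.28√SJC28 + 0.36 ln(CRP+1) + 0.014 GH + 0.96`) with the
  remission (< 2.6) / low (< 3.2) / moderate (≤ 5.1) / high cut-offs, and
  expansion of records into the d = 58 item representation.
* **Unsupervised structure** — PCA of the z-standardized components and an
  emergent self-organizing map (4,000 neurons on a 50 × 80 toroidal grid)
  with U-matrix (distance structure), P-matrix (Pareto-radius hypersphere
  density) and U\*-matrix (density-rescaled distance), plus automated
  valley/crater cluster and outlier extraction and a χ² test of clusters
  against stages.
* **Generative augmentation** — density-guided synthesis of valid new cases
  around seed patients (Gaussian perturbation, accepted with the P-matrix
  existence probability inside the seed cluster's basin) to equalize
  cluster sizes so 1–2-patient subgroups become learnable.
* **Supervised distillation** — random-forest permutation importance,
  computed ABC (cABC) categorization into the "important few", and 4 × 25
  nested Monte-Carlo cross-validation with balanced accuracy / ROC-AUC and
  a permuted-feature overfitting control.
* **Association statistics** — quartile rescaling, Pearson χ², and
  Kruskal–Wallis tests for stage/therapy questions.
* **Synthetic cohort generator** — comparable patient data are
  confidential, so a calibrated generator (59/16/5 stage mixture of n = 80,
  a planted tenderness signal in the right index-finger MCP joint with odds
  ratio 8 in active disease, three injected outlier patients) stands in as
  a first-class, tested module.

## Worked example: the analysis workflow

The numbered scripts under `analysis/` run the whole study on the synthetic
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # cohort: 80 patients + 3 outliers
Rscript analysis/02_score.R           # DAS28-CRP scores and stages
Rscript analysis/03_structure.R       # PCA, ESOM, U/P/U* matrices, clusters
Rscript analysis/04_augment.R         # generative cluster equalization
Rscript analysis/05_select_items.R    # d = 58 item distillation
Rscript analysis/06_cluster_features.R# per-cluster component attribution
Rscript analysis/07_associations.R    # quartile / stage associations
```

Output of step 3 (seed 42):

```
cluster sizes (outlier groups separated):
       cluster_1        cluster_2  outlier_group_3  outlier_group_4 ...
              63               10                2                2
cluster vs stage: chi-square = 45.67, df = 2, p = 1.21e-10
```

The map recovers the stage structure (χ² on the cluster × stage table of
clusters with ≥ 5 members) and isolates the injected swollen-dominant
outlier pair as its own group. Step 5 then distills the items:

```
reduced feature set (cABC set A): crp, gh, tender_mcp2_right, ...
full_58_items            BA 0.82 (0.66-0.93)  roc-auc 0.95 (0.89-1.00)
reduced_set              BA 0.82 (0.68-0.93)  roc-auc 0.95 (0.90-1.00)
sparse_set               BA 0.79 (0.63-0.90)  roc-auc 0.85 (0.74-0.98)
original_4_components    BA 0.86 (0.71-1.00)  roc-auc 0.97 (0.83-1.00)
reduced_set_permuted     BA 0.50 (0.28-0.72)  roc-auc 0.54 (0.13-0.90)
```

Reading: a handful of items — including the planted signal joint,
tenderness of the right MCP-2 — classify remission vs active disease as
well as all 58 items (median balanced accuracy 0.82, 95% interval from 100
nested cross-validation runs), while the permuted-feature control sits at
the 0.50 chance level, showing the pipeline does not overfit. Step 6
attributes each (equalized) cluster to its dominant component; the
injected swollen-dominant outlier group is identified by the swollen joint
count alone with balanced accuracy 1.00.

## Package layout

`R/` implementation (one file per analysis stage) · `analysis/` the
numbered workflow drivers · `tests/testthat/` unit, property and
end-to-end tests · `vignettes/das28map-methods.Rmd` the methods notes:
model assumptions, parameter defaults and their rationale, degenerate-input
conventions, limitations.
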
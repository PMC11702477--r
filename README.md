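# cytoien

Immune feature matrices and prior-weighted elastic-net classification for
mass-cytometry cohorts.

## What problem this solves

Single-cell mass cytometry (CyTOF) measures dozens of protein markers on
each of hundreds of thousands of peripheral immune cells per subject.
Turning those per-cell tables into a subject-level diagnostic — e.g.
separating dementia patients from healthy controls using blood alone —
requires a chain of steps that is easy to get subtly wrong at small cohort
sizes: cell-type assignment, per-subject feature extraction, feature
selection, and honestly cross-validated classification. `cytoien`
implements that chain for R users analysing cytometry cohorts, together
with a synthetic cohort generator with planted ground truth so every stage
can be validated end to end without patient data.

The stages:

* **Clustering & annotation** — pooled cells on a k-nearest-neighbour
  graph, Leiden modularity communities, clusters annotated to the leaves of
  a three-tier immune taxonomy (4 lineages / 6 intermediate subsets / 29
  leaf subtypes by default) by cosine similarity to per-leaf marker
  signatures.
* **Feature matrix** — per subject, 39 tiered abundance fractions plus the
  median arcsinh-transformed intensity of each of 41 feature markers in
  each of the 29 leaves: 39 + 41 × 29 = **1228 features**, z-scored per
  feature.
* **Feature selection** — Spearman rank correlation of every feature with
  the binary group label; the leading block of the p-sorted list is taken
  at the inflection of the cumulative −log10(p) curve (the two-segment
  breakpoint of the curve; degenerate curves fall back to p < 0.05).
* **Classifier** — the immunological elastic net: penalised logistic
  regression minimising

  ```
  -(1/n) loglik + lambda * sum_j w_j ( alpha |beta_j| + (1-alpha)/2 beta_j^2 ),
  w_j = 1 - s_j (1 - exp(-phi))
  ```

  with per-feature penalty factors `w_j` derived from prior scores
  `s_j ∈ [0,1]` (`phi = 0` gives the standard elastic net), fitted by its
  own C++ coordinate-descent solver and evaluated by repeated stratified
  10-fold cross-validation; aggregated out-of-fold predictions yield the
  rank-based AUC and a Mann–Whitney p-value (AUC = U / (n1·n2) exactly).

## Worked example

Simulate a two-group cohort with three planted marker effects
(standardised subject-level effect size 2), build the feature matrix with
ground-truth cell labels, select features, and fit the classifier:

```r
library(cytoien)

cfg <- cohort_config(n_subjects_per_group = c(AD = 14, HC = 18),
                     n_cells_per_subject = 500, seed = 42)
cfg <- plant_marker_effects(cfg,
  subtypes = c("M01", "T01", "NK02"),
  markers  = c("IKBa", "pSTAT3", "pERK1_2"),
  group = "AD", effect_size = 2)
cohort <- generate_cohort(cfg)

fm <- featurize(oracle_assign(cohort), pool_cells(cohort$cells),
                cohort$taxonomy, subjects = cohort$meta$subject_id)
labels  <- factor(cohort$meta$group, levels = c("AD", "HC"))
ranking <- select_inflection(rank_features(fm, labels))
fit <- ien(fm$values[, ranking$feature[ranking$selected], drop = FALSE],
           labels, n_repeats = 10, seed = 43)
print(fit)
summary(fit)
```

```
Immunological elastic net (10x 10-fold CV, alpha = 0.5, phi = 0)
  aggregate AUC: 0.960   Mann-Whitney p: 5.9e-07
  nonzero features (final fit): 75 of 157

aggregate AUC 0.960 (per-repetition 0.921-0.976, sd 0.018)
Mann-Whitney two-sided p: 5.9e-07
most frequently selected features:
   NK02__pERK1_2        M01__IKBa      T01__pSTAT3 ...
               1                1                1
```

Reading the output: the aggregate AUC (0.960) is the rank separability of
the two groups by the per-subject predictions averaged over 10 repetitions
of 10-fold cross-validation; the Mann–Whitney p tests those aggregated
predictions between groups; the selection frequencies show that the three
planted features (`NK02__pERK1_2`, `M01__IKBa`, `T01__pSTAT3`) are kept by
every cross-validation fit. `plot(fit)` draws the ROC curve,
`coef(fit)` returns the final full-data coefficients, and
`predict(fit, newx)` scores new subjects.

`run_model_pair()` wraps the whole chain for one group pair (writing the
feature matrix, ranking, model JSON and a manifest), and
`compare_biomarkers()` tabulates the model AUC against scalar plasma
biomarkers (each alone and combined by a two-feature logistic score).
Descriptive statistics follow the cytometry-paper conventions:
`compare_two_groups()` gates a t-test vs Mann–Whitney on Kolmogorov–Smirnov
normality, `compare_three_groups()` gates ANOVA vs Kruskal–Wallis, and
`subset_correlations()` builds per-group Spearman correlation matrices of
subtype abundances for heatmap display.

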
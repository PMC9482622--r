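# shapboost

Explainable gradient tree boosting for family-structured cohort studies of
substance use.

## The problem

Cohort studies of cannabis use and dependence ask two questions at once:
*how well* can use levels and a dependence diagnosis be classified from
multimodal data (environment, personality, mental health, neurocognition,
brain structure and connectivity), and *which* factors do the classifying —
overall, and differently in men and women. The data that motivate this
package have three awkward properties: the diagnosis is rare (~9%
prevalence) and male-skewed; participants come in families, so naive
cross-validation leaks information between relatives; and features number
in the hundreds, are correlated in domains, and have missing entries.

`shapboost` implements that full analysis as reusable, tested R functions:

* **`gbt()`** — a compact second-order gradient tree boosting classifier
  (logistic loss, exact greedy splits, sparsity-aware missing-value
  routing, subsampling, early stopping), returning a classed model with
  `print`/`summary`/`predict`/`plot` methods and full tree access. Each
  round fits a tree to the loss gradients with split gain
  ½[G²_L/(H_L+λ) + G²_R/(H_R+λ) − (G_L+G_R)²/(H_L+H_R+λ)] and leaf values
  −ηG/(H+λ).
* **Shapley machinery** — exact subset-enumeration attributions
  (`shapley_exact`), a polynomial-time weighted-path traversal
  (`shapley_fast`), and pairwise Shapley interaction values
  (`shapley_interactions`) with path-dependent, cover-weighted coalition
  values; local accuracy φ₀ + Σφⱼ = margin holds to machine precision.
* **Family-blocked nested cross-validation** (`family_folds`, `nested_cv`)
  with the 75-point learning-rate × depth × subsample grid, inner-loop AUC
  selection, and honest outer estimates.
* **Ranking and reporting** (`global_importance`, `median_rank`,
  `sex_interaction_report`) — normalized mean-|SHAP| importances,
  cross-model median ranks (≤ 20 flags consistent factors), and a
  sex-interaction table thresholded at 0.1 of a model's total attribution
  with small/moderate/large/very-large effect bins.
* **Brain features** (`fisher_z`, `proportional_threshold`,
  `nodal_global_efficiency`, `nodal_local_efficiency`,
  `network_block_features`, `cohen_d_field`, `find_clusters`) — graph
  efficiency on proportionally thresholded connectomes, within/between
  network connectivity, and effect-size-thresholded activation clusters.
* **A synthetic cohort generator** (`simulate_cohort`) — family blocks,
  correlated feature domains, calibrated ordinal use and dependence
  outcomes from a latent liability model with planted main and
  sex-interaction effects, and injected missingness — so the whole pipeline
  is testable without any restricted data.
* **A pipeline** (`run_pipeline`) tying it together with delimited-text
  artifacts and a JSON manifest that reproduces a run byte-for-byte.

## Worked example

```r
library(shapboost)
coh <- simulate_cohort(n = 600, seed = 8)   # default planted effects
mean(coh$dependence)
#> 0.092

x <- cohort_features(coh)                   # sex + 25 feature columns
y <- binarize_outcomes(coh$use_category, coh$dependence)$use10plus

cv <- nested_cv(x, y, coh$family_id, grid = reduced_grid(),
                seed = 2, nrounds = 200)
cv
#> Nested 5-fold CV: mean outer AUC 0.756 (folds: 0.700, 0.857, 0.773, 0.771, 0.678)

expl <- explain_models(cv, x)               # out-of-fold Shapley values
head(median_rank(lapply(expl, function(e) global_importance(e$phi))), 5)
#>             factor median_rank highly_ranked
#> 1    personality_1           1          TRUE
#> 2  mental_health_1           2          TRUE
#> 3              sex           3          TRUE
#> 4  environmental_1           4          TRUE
#> 5 neurocognitive_1           5          TRUE

sex_interaction_report(expl)
#>          factor     value      bin    mean_men mean_women main_importance
#> 1 personality_1 0.2094425 moderate -0.06295939 0.02214442       0.1723182
```

The generator planted main effects on `environmental_1`,
`mental_health_1`, `neurocognitive_1` and a men-only effect on
`personality_1`: the median ranks recover all four ahead of the 21 null
features, and the sex-interaction report flags exactly the planted
interaction (normalized value 0.21, a "moderate" effect; opposite signed
attributions in men and women). An out-of-fold AUC of ~0.76 for the 10+
outcome at n = 600 is what this effect size supports; null cohorts score
~0.5 (see the test suite).

Descriptive anchors work directly from published count tables:

```r
chi_square_contingency(rbind(c(81, 28), c(468, 627)))$statistic
#> 39.83485
pooled_t_from_summary(109, 4.39, 2.37, 1090, 5.06, 2.14)$statistic
#> 3.085212
```

## Documentation

The methods vignette (`vignettes/shapboost-methods.Rmd`) explains the
liability generator and its calibration, the boosting and Shapley
algorithms and their numerical conventions, the family-blocked
cross-validation design, and the known limitations. Every exported
function carries roxygen documentation with examples.
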
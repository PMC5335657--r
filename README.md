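# smtl

Joint feature selection and longitudinal prediction of clinical cognitive
scores from baseline imaging features.

## The problem

In neurodegenerative disease cohorts (the motivating case is Alzheimer's
disease progression), each subject has a baseline MRI summarized as a vector
of ROI volumetric features (e.g. 93 gray-matter region volumes), and clinical
cognitive scores such as ADAS-Cog and MMSE measured at several future time
points (baseline, 6, 12, 24 months). The scientific question is twofold:
which small set of baseline brain regions predicts the *whole trajectory* of
cognitive decline, and how well can future scores be predicted from baseline
imaging alone?

Fitting one sparse regression per score and per time point ignores three
strong sources of shared structure: correlated features (neighboring or
bilateral regions atrophy together), similar subjects (who should receive
similar predictions), and correlated score types (ADAS-Cog and MMSE track
the same decline). `smtl` fits all T×C prediction tasks jointly.

## The model

Let `X ∈ R^{S×F}` be the z-normalized baseline features and
`Y^(t) ∈ R^{S×C}` the scores at time point t. The package estimates weight
matrices `W^(t) ∈ R^{F×C}` by minimizing

```
sum_t || Y^(t) − X W^(t) ||_F²
  + λ₁ sum_t [ Tr(W^(t)ᵀ L_f W^(t))            (feature–feature smoothness)
             + Tr((X W^(t))ᵀ L_s X W^(t))      (subject–subject smoothness)
             + Tr(W^(t) L_c^(t) W^(t)ᵀ) ]      (score–score smoothness)
  + λ₂ || Ŵ ||_{2,1}
```

where `L_f`, `L_s`, `L_c^(t)` are unnormalized graph Laplacians of
heat-kernel similarity graphs (`exp(−‖a−b‖²)`) over feature columns, subject
rows and score columns, and `Ŵ = [W^(1) … W^(T)] ∈ R^{F×C·T}` is the
unfolded weight matrix whose l2,1 norm (sum of row norms) zeroes entire
rows — selecting a *common* feature set across every time point and score.

The optimizer alternates closed-form Sylvester-equation solves
`A W^(t) + W^(t) B^(t) = XᵀY^(t)` (both sides symmetric, solved spectrally)
with iterative reweighting of the l2,1 term; the objective decreases
monotonically and typically converges in ~10 iterations. Features are then
ranked by unfolded row norm, and the selected columns feed one linear
epsilon-SVR (cost 1, epsilon 0.1, unit-norm subject vectors) per
(time, score) cell. Evaluation is nested cross-validation: 10 outer folds,
an inner 5-fold grid search for (λ₁, λ₂), Pearson correlation and RMSE per
cell, plus a per-task Lasso baseline (`lasso_baseline()`) and
selection-stability reports across folds (`region_frequency_report()`).

## Worked example

```r
library(smtl)

cohort <- simulate_cohort(simulation_spec(n_subjects = 120, n_features = 93,
                                          support_size = 10), seed = 42)
fit <- smtl_fit(cohort$x, cohort$y, lambda1 = 1, lambda2 = 5)
print(fit)
#> smtl_fit: S=120 F=93 C=2 T=4  lambda1=1 lambda2=5
#>   8 iterations, converged=TRUE, final objective 179.898
#>   active rows (rel. threshold 1e-3): 93 / 93

rank_features(fit, rule = "top_k", k = 10)$selected
#> 22 25 33 38 45 49 50 57 60 90     # == cohort$support, the planted truth

rep <- smtl_cv(cohort$x, cohort$y, lambda1_grid = c(0.1, 1),
               lambda2_grid = c(1, 10), n_folds = 10, inner_folds = 3,
               seed = 42)
print(rep)
#> smtl cross-validation report (10 folds, seed 42)
#>       time   score mean_corr sd_corr mean_rmse sd_rmse
#> 1 baseline score_1     0.772  0.0748     0.698  0.1418
#> 2      M06 score_1     0.693  0.1767     0.871  0.2027
#> 3      M12 score_1     0.786  0.1009     0.844  0.2085
#> 4      M24 score_1     0.683  0.1584     0.916  0.2144
#> 5 baseline score_2     0.699  0.1707     0.795  0.0955
#> 6      M06 score_2     0.765  0.1205     0.803  0.1499
#> 7      M12 score_2     0.749  0.1341     0.888  0.1201
#> 8      M24 score_2     0.763  0.1210     0.878  0.2089
```

The fitted top-10 ranking recovers the planted 10-feature support exactly;
held-out correlations around 0.7–0.8 at noise sd 0.5 (signal sd 1) are the
expected ceiling for this signal-to-noise ratio.

The same pipeline is scriptable from the shell:

```sh
Rscript inst/cli/smtl.R simulate --seed 7 --out-dir data
Rscript inst/cli/smtl.R cv --features data/features.csv --scores data/scores.csv \
    --seed 7 --out-dir out --lambda1-grid 0.1,1 --lambda2-grid 1,10
Rscript inst/cli/smtl.R report-regions --report out/cv_report.json --out regions.tsv
```

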
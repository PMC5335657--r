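---
title: "Multi-relational temporally constrained learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-relational temporally constrained learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtl)
```

## The model

`smtl` addresses longitudinal prediction of clinical cognitive scores (such
as ADAS-Cog and MMSE) at several future time points from baseline imaging
features alone. With `X` the S×F z-normalized baseline matrix and `Y^(t)`
the S×C scores at time point t, the estimator minimizes

$$\sum_t \|Y^{(t)} - XW^{(t)}\|_F^2
 + \lambda_1 \sum_t \big[\mathrm{Tr}(W^{(t)\top} L_f W^{(t)})
 + \mathrm{Tr}((XW^{(t)})^\top L_s XW^{(t)})
 + \mathrm{Tr}(W^{(t)} L_c^{(t)} W^{(t)\top})\big]
 + \lambda_2 \|\hat W\|_{2,1}$$

over the per-time weight matrices. The three quadratic terms encode the
modeling assumptions: feature columns that are close in the data should
receive similar weight rows; subjects that are close should receive similar
predicted scores; score types whose observed columns are close should have
similar weight columns. The l2,1 term on the unfolded matrix
$\hat W = [W^{(1)},\dots,W^{(T)}]$ zeroes whole rows, so a feature is kept
or discarded *jointly* for every time point and score type — the core
premise being that the biologically meaningful support is stable along the
trajectory.

Assumptions worth stating explicitly: complete data (no imputation — missing
cells are errors), a linear score model per task, time points as discrete
ordered stages (no date arithmetic), and similarity graphs that are
meaningful in the z-normalized feature space.

## Graphs and numerical conventions

* **Heat kernel.** Similarity between vectors is $\exp(-\|a-b\|^2)$, exactly
  as the model defines it, with no bandwidth. On large dimensions squared
  distances concentrate and all off-diagonal similarities can underflow
  toward zero; the graphs then degenerate gracefully (Laplacians ≈ 0 and
  $\lambda_1$ becomes inert, leaving the sparse regression). An optional
  bandwidth `sigma` rescales the exponent to $-\|a-b\|^2/(2\sigma^2)$ for
  users who want non-trivial graphs at high dimension; it is deliberately
  `NULL` by default for fidelity. (The two conventions coincide at
  $\sigma = 1/\sqrt 2$, not at $\sigma = 1$, which is why the default is "no
  bandwidth" rather than a number.)
* **Laplacian convention.** `L = D − S` with `D` the diagonal of row sums of
  the similarity matrix `S`. Diagonal self-similarities (always 1) cancel in
  the subtraction, so self-loops need no special handling. Only this
  orientation makes all three regularizers positive semidefinite and the
  objective convex; the trace form equals exactly half the explicit pairwise
  double sum $\sum_{u,v} s_{uv}\|d_u - d_v\|^2$, and $\lambda_1$ absorbs the
  factor of two. Tests assert this identity to 1e-10 on random instances.
* **l2,1 handling.** The norm is non-smooth at zero rows, so the solver uses
  iterative reweighting: a diagonal matrix with entries
  $1/(2\max(\|\hat w_{i,:}\|_2, \varepsilon))$, $\varepsilon = 10^{-8}$
  (configurable). The induced quadratic penalty majorizes the l2,1 norm up
  to a constant, which gives the monotone-descent guarantee. Reweighting
  never produces exact zeros — this drives the selection rule below.

## The optimizer

Setting the gradient to zero gives, per time point, the Sylvester equation

$$\big(X^\top X + \lambda_1 L_f + \lambda_1 X^\top L_s X + \lambda_2 L_D\big) W^{(t)}
 + W^{(t)} \big(\lambda_1 L_c^{(t)}\big) = X^\top Y^{(t)}.$$

Both coefficient matrices are symmetric, so each solve is spectral: one F×F
and one C×C eigendecomposition, dividing the rotated right-hand side by
pairwise eigenvalue sums. A system is declared singular when an eigenvalue
sum vanishes (possible only when both sides are singular, e.g.
$\lambda_1 = \lambda_2 = 0$ with rank-deficient $X^\top X$); the error
message points at the configurable ridge. The independent correctness check
in the tests is a dense Kronecker-vectorized solve, which the solver itself
never uses.

Iteration details, each a deliberate choice:

* **Initialization**: ridge least squares
  $W^{(t)}_0 = (X^\top X + 10^{-3} I)^{-1} X^\top Y^{(t)}$ — well-defined
  when F > S and close to the intended "linear model" start.
* **Reweighting schedule**: the l2,1 diagonal $L_D$ is refreshed from the
  current unfolded weights *before each time-point solve* (Gauss–Seidel),
  not once per outer sweep. Each solve still exactly minimizes the current
  majorizing surrogate, so descent is preserved, and the tail of the
  iteration converges noticeably faster.
* **Stopping**: after each sweep the iteration stops when either the
  Frobenius change of $\hat W$ or the relative objective decrease falls
  below `tol` (default 1e-6), with a hard cap of 50 sweeps. The dual rule
  exists because an *absolute* objective threshold is scale-broken (the
  objective is O(hundreds) on realistic cohorts) while the weight-change
  test alone can take 50+ sweeps at large $\lambda_2$ even though the
  objective plateaued after ~10; the relative-objective arm is what
  "iterate until the objective converged" means at this scale.
* **Graph scheduling**: $L_f$, $L_s$ are built once from the training
  feature matrix, $L_c^{(t)}$ once per time point from the training scores,
  and only $L_D$ changes across iterations.

## Feature selection and prediction

Features are ranked by unfolded row norm, ties broken by ascending original
index (deterministic). Because reweighting leaves tiny rather than exact
zeros, the default selection keeps rows above `1e-3` of the maximum row
norm; a `top_k` rule is available when a fixed budget is wanted.

Prediction uses one linear epsilon-SVR per (time, score) cell on the
selected columns, with each subject's selected feature vector scaled to unit
Euclidean norm first. Parameters are the classic toolbox defaults — cost 1,
epsilon 0.1, linear kernel. No pre-installed R package provides
epsilon-SVR, so the package solves the primal quadratic program exactly with
`quadprog` (a 1e-8 diagonal jitter on the intercept and slack variables
makes the Hessian positive definite without measurably moving the solution);
during development the solver was validated against the libsvm reference
implementation to ~1e-6, and those oracle coefficients are frozen in the
test suite. Constant training targets are flagged and predicted as the
constant rather than erroring.

## Cross-validation protocol

Ten outer subject-level folds (seeded; sizes differ by at most one). Within
each outer training fold, a 5-fold inner search over the
$(\lambda_1, \lambda_2)$ grid — default $10^{-3} \dots 10^{3}$ — picks the
pair minimizing mean validation RMSE summed over all T×C cells, ties going
to the first grid entry (deterministic). The winning pair is refit on the
whole training fold; one shared feature set is selected and used by every
cell in that fold.

Leakage discipline: normalization statistics, all similarity graphs
(including the score graphs, built from training-fold scores only — the
leakage-safe reading of an underspecified point), and hyperparameter
choices are computed from training rows exclusively, inner folds
re-normalize with inner-training statistics, and the per-fold report records
enough (centers, scales, graph fingerprints, chosen λ, selection) for the
test suite to verify bit-identity under test-row perturbation. Pearson
correlations on constant vectors are reported as `NA` with a warning, never
imputed as 0.

The per-task baseline (`lasso_baseline()`) runs the identical protocol with
an independent l1-penalized selection per cell (glmnet; the penalty is the
smallest-CV-error value whose selection is non-empty), followed by the same
SVR stage.

A single shared $\lambda_1$ multiplies all three relational terms, as the
model defines it; per-term weights were considered and rejected to keep the
printed objective.

## The synthetic cohort generator

The generator produces exactly the structures the three regularizers target,
so every pipeline stage is testable without clinical data:

* **Features**: blocks of 10 consecutive features share a Gaussian factor
  giving within-block correlation 0.3 (defaults; S = 200, F = 93 mirror a
  realistic ROI cohort), then z-normalization.
* **Support**: `support_size = 10` rows are nonzero, identical at every time
  point; off-support rows are exactly zero.
* **Temporal structure**: weights at time t are the baseline weights scaled
  by $1 + 0.1(t-1)$ plus a small N(0, 0.05) on-support perturbation — smooth
  trajectories whose signal grows with t, matching the observation that
  later time points are easier to predict.
* **Score correlation**: the baseline weight columns are linearly
  recombined so the noiseless signals have *exactly* unit variance and
  pairwise correlation 0.6, and the additive noise (sd 0.5, i.e.
  signal-to-noise 2) carries the same correlation; the observed score
  correlation therefore matches the target up to Monte-Carlo error, which
  the tests check at S = 2000.
* **Group labels**: NC/MCI/AD terciles of the first score's baseline signal,
  so sub-group mechanics can be exercised; no claim is made that they mimic
  real diagnostic strata.

What the generator does **not** emulate: measurement floors/ceilings of real
cognitive scales, missing visits, site effects, non-Gaussian atrophy
patterns, or MCI-to-AD conversion dynamics. A green test on this generator
establishes that the machinery is correct under the model's own assumptions,
not that real-cohort accuracy figures are reproduced — those require
restricted clinical data and are explicitly out of scope.

## Acceptance properties

Because no numeric targets are reproducible at desk scale, acceptance is
property-based (`tests/testthat/test-acceptance.R`): Sylvester-solver
agreement with the Kronecker oracle (1e-9, 100 instances); monotone,
convergent objective traces across the 4×4 λ grid on the default cohort;
the λ = 0 least-squares limit (1e-6); trace/double-sum identities (1e-10,
50 instances); recovery of the planted 10-feature support in ≥ 18/20
replicates at the stated sizes; the joint selector beating per-task Lasso in
≥ 15/20 seeds (run at S = 60, F = 40 — satisfying the stated F > S/2 — with
a single split and a small inner grid per seed, to fit the time budget; the
criterion fixes the outcome, not the per-seed protocol); a leakage audit;
and byte-identical simulate + cv reruns.

## Known limitations

Single-modality features; no missing-data handling (stated model
assumption); unnormalized Laplacians only; dense solvers sized for
F in the hundreds, not voxelwise inputs; the default heat kernel is
near-degenerate at large S or F (see `sigma` above); and the comparator is
restricted to a plain Lasso — temporal-group-lasso variants are out of
scope.
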
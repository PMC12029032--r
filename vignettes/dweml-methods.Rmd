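---
title: "Double-weighted ensemble classification of metabolomics tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-weighted ensemble classification of metabolomics tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dweml)
```

## The problem

Untargeted metabolomics assays quantify hundreds of metabolites in cohorts
that rarely exceed a few dozen subjects. Classifying such *wide-short*
tables (features ≫ samples) with a single model is brittle: different
learner families fail on different datasets, and small-sample accuracy
estimates are noisy. `dweml` combines nine classifier families into one
signed, doubly weighted vote, so that globally weak learners and
individually hesitant predictions are both attenuated, and wraps the
combiner with the pretreatment, augmentation and validation stages a
metabolomics analysis needs.

## The model

Each base classifier family $j$ is cross-validated (stratified $k$-fold,
default $k = 10$) on the pretreated, augmented table. For every sample $i$
the held-out model emits two complementary class-membership scores
$p^{\mathrm{Case}}_{ij} + p^{\mathrm{Control}}_{ij} = 1$, from which we keep

- the predicted class (Case iff $p^{\mathrm{Case}} > 0.5$; the exact tie
  predicts Control, conservatively toward the reference class),
- the prediction score $s_{ij} = \max(p^{\mathrm{Case}}, p^{\mathrm{Control}})$,
- the classification confidence $c_{ij} = |p^{\mathrm{Case}} - p^{\mathrm{Control}}|$,
  the distance from the classification margin.

Families whose pooled out-of-fold accuracy $a_j$ reaches the **accuracy
gate** (0.60, inclusive) join the ensemble. The vote of classifier $j$ on
sample $i$ is

$$v_{ij} = \sigma_{ij}\, s_{ij}\, a_j\, c_{ij}, \qquad
  \sigma_{ij} = \begin{cases} +1 & \text{Case call} \\ -1 & \text{Control call,}\end{cases}$$

and the ensemble score is $E_i = \sum_j v_{ij}$, bounded by the number of
selected classifiers. An ROC curve over the real samples' out-of-fold
ensemble scores (candidate thresholds: midpoints between consecutive
distinct scores plus $\pm\infty$ sentinels; Case iff $E \ge t$) yields the
Mann–Whitney AUC (tied pairs count 1/2), and the decision cutoff $t^\*$
maximizes the Youden index $J = \mathrm{TPR} - \mathrm{FPR}$, ties broken
toward higher sensitivity and then the lower threshold. Rates are reported
with binomial Wald standard errors $\sqrt{p(1-p)/m}$ on their own
denominators.

Two readings deserve flagging. "Prediction score" and "classification
confidence" are not separately standardized concepts for probabilistic
learners; we take the natural two-class readings above ($s$ = top-class
score, $c$ = score gap), and calibrate margin outputs (linear large-margin,
kernel SVM) to $[0,1]$ by Platt scaling fitted within the training folds so
$c$ is well defined everywhere. Second, the ROC is computed from
**out-of-fold** votes, so the reported AUC/accuracy are cross-validated;
deployment (`predict()`) uses full-data refits with the stored weights
$a_j$ and the stored cutoff.

## Pretreatment

Recipes are ordered compositions of four steps, applied to the full table
before cross-validation:

| step | effect | default parameters |
|---|---|---|
| `total_area` | each row divided by its sum | rows must have positive sums |
| `log10` | elementwise $\log_{10}$ | zeros are an error; opt-in half-minimum offset |
| `autoscale` | per column: center, divide by SD | sample ($n-1$) SD |
| `pareto` | per column: center, divide by $\sqrt{\mathrm{SD}}$ | as above |

The sample SD is used throughout (the metabolomics-literature convention);
constant columns scale to zero with a warning rather than NaN. The log10
zero policy defaults to a hard error so data are never silently altered;
`half_min_positive` adds half the smallest positive value of the table
first. Fitting pretreatment on the full dataset before CV mirrors the
standard workflow order; it leaks mild distributional information across
folds, which matters little for scaling transforms but is worth knowing.

## SMOTE augmentation

Training requires a minimum cohort of 100 samples (`smote_target_total`).
Deficits are filled with SMOTE: a synthetic row is $x + u(x_{nn} - x)$ with
$x$ a real row of the class (chosen cyclically for even coverage), $x_{nn}$
one of its $k = 5$ Euclidean same-class nearest neighbors and
$u \sim U(0,1)$. The policy is two-phase: balance the minority class up to
the majority size, then grow both classes equally (odd remainder to Case)
until the total reaches the target. Interpolation always uses *real* rows
as endpoints, so every synthetic sample lies exactly on a segment between
two real same-class samples — a testable geometric contract — and real rows
are never modified. Synthetic rows participate in training and CV folds but
are excluded from every reported metric (ROC, confusion matrix, rates):
their denominators are real samples only.

A consequence worth stating plainly: because synthetic rows are interpolates
of real rows and share their labels, a held-out real sample often has
near-copies of itself in the training folds. On signal-free data this
leakage alone can push out-of-fold AUC far above 0.5. That is a property of
the augment-then-cross-validate order, not of the combiner; the package
therefore measures null behavior on cohorts generated at full size (no
augmentation), and the permutation check — which breaks the label link —
remains the guard against overfitting on augmented runs.

## Optimization stages

*Grid search* evaluates compact per-family grids (shipped in
`inst/extdata/default_grids.yaml`, ≤ 18 points per family, capped at 512)
by the same stratified CV and picks the highest accuracy, earliest grid
point on ties. *Feature selection* is a wrapper GA over binary masks:
population 50, tournament selection of size 3, uniform crossover (rate
0.9), per-bit mutation ($1/p$ by default), elitism of one, the all-ones
mask seeded into generation 0, fitness = cross-validated accuracy of a fast
ridge-logistic probe (a pure-accuracy criterion; no parsimony term). The
search stops at 40 generations or 400 s, whichever comes first, and is
fully deterministic (seed 1992 by default) when the generation cap binds.
One mask is shared by all families. The upstream tool's "maximum function
complexity" control has no portable meaning and is deliberately not
emulated; the generation cap is the practical complexity bound. Neither
stage is nested inside the outer CV — the optimistic-bias risk this carries
is the price of matching the workflow being modeled, and the permutation
check is the corresponding control.

The four standard configurations (both stages, each alone, neither) are
driven by `run_all_configs()` / `train --all-configs`.

## Permutation check

`permutation_test()` permutes labels uniformly over all rows of the
augmented table (class counts preserved exactly), re-runs whatever the
configuration enables (FS/optimization included) and the nine-family CV,
and passes only if *no* accuracy reaches the gate in any of the $n = 5$
permutations. Keep the statistics of this criterion in mind: at $n = 100$
samples a single CV accuracy under permuted labels is roughly
$\mathrm{Binomial}(100, \approx 0.5)/100$ (SD ≈ 0.05), so the maximum of
$9 \times 5 = 45$ such accuracies exceeds 0.60 with appreciable probability
even for a perfectly sound pipeline. A failed permutation check on a small
cohort is therefore a prompt to inspect the margin, not a verdict; with
$n = 5$ permutations no p-value machinery is attempted.

## Synthetic data generator

`simulate_feature_table()` emulates the statistical shape of case-control
metabolomics tables: per-sample latent Gaussian profiles with
block-exchangeable correlation (blocks of 10 features, $\rho = 0.2$,
standing in for co-regulated metabolite groups), a Case shift of
`effect_size_sd` within-class SD units on the informative coordinates, and
intensities $10^{\mu + \sigma z}$ with $\mu = 5$, $\sigma = 0.4$ — positive,
right-skewed values spanning roughly two decades, so total-area and log10
steps operate on realistic input. The defaults (30/30 samples, 200
features, 10 informative, effect 2 SD) are the package's reference study
conditions. The effect is injected on the latent log scale, so autoscale
and Pareto recipes see comparable effect sizes. The generator does **not**
mimic LC-MS missingness, NMR binning artifacts, batch drift or heavy-tailed
contamination; passing tests on simulated data demonstrate the machinery's
correctness and sane statistical behavior, not field performance on any
real cohort.

## Numerical and design choices

- **Determinism.** One master seed; every stage (folds, each fit, SMOTE,
  GA, each permutation) uses a seed derived by hashing the master seed with
  a stage tag (`derive_seed()`), so stages rerun reproducibly in isolation.
  Stochastic learners receive per-family, per-fold seeds.
- **Degenerate inputs.** Zero-variance features: dropped inside the naive
  Bayes wrapper (Gaussian NB is undefined there), scaled to zero with a
  warning in autoscale/Pareto, harmless elsewhere. Single-feature masks are
  padded with a zero column for the penalized-logistic fit. Zero-denominator
  rates report NaN (serialized as JSON null), never 0.
- **Tie-breaks.** Exact score ties predict Control; Youden ties prefer
  higher TPR then lower threshold; grid ties prefer the earliest point.
- **Labels.** File labels map to Case/Control only through an explicit
  user-supplied mapping — the sign convention of the vote depends on which
  class is "Case", so guessing is refused. Missing values are rejected, not
  imputed.
- **GLM vs LR.** The two logistic families are retained as distinct presets
  (ridge vs lasso penalty) for ensemble diversity; whether the original
  workflow's pair differed beyond solver choice is not determinable, and
  two differently regularized linear voters are useful regardless.
- **Problem sizes.** The shipped tests exercise the full pipeline at the
  reference conditions (100 × 200 after augmentation, 10-fold CV, nine
  families), the null analysis over 20 seeds, 20 repeated permutation
  checks, and the four-configuration determinism check on a 40-feature
  table with a reduced GA (population 8, 3 generations) — determinism does
  not depend on search effort.

## Known limitations

- Augment-then-validate leakage (above) inflates out-of-fold metrics
  whenever SMOTE actually adds rows; the permutation check is the control.
- FS/HPO are not nested in the outer CV; reported accuracies of optimized
  configurations carry selection optimism.
- The permutation pass/fail criterion at the 60% gate is noisy at
  $n \approx 100$ (see above) and `n_permutations = 5` gives it little
  resolution.
- The ensemble score is a signed vote sum, not a calibrated probability; no
  multi-class extension is provided.
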
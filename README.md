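# dweml — double-weighted ensemble machine learning for metabolomics

Untargeted metabolomics classifiers are trained on *wide-short* tables: a few
dozen samples, hundreds of metabolite intensities. Single models (and the
field's PLS-DA workhorse) are fragile in that regime. `dweml` implements a
double-weighted soft-voting ensemble for binary Case/Control classification
of such tables, together with the pretreatment, augmentation, optimization
and overfitting checks that surround it:

- **Pretreatment recipes**: total-area normalization, log10 transformation,
  autoscaling, Pareto scaling, composed in any order.
- **SMOTE augmentation** to a 100-sample minimum cohort with a class-balance
  phase, synthetic rows flagged and excluded from all reported metrics.
- **Nine base classifier families** (NB, GLM, LR, FLM, DL, DT, RF, GBT, SVM)
  under stratified 10-fold cross-validation; only families with CV accuracy
  ≥ 60% join the ensemble.
- **Double-weighted voting**: classifier *j*'s vote on sample *i* is
  `v_ij = σ_ij · s_ij · a_j · c_ij`, where `s_ij` is the prediction score of
  the predicted class, `a_j` the classifier's cross-validation accuracy,
  `c_ij` the classification confidence (the gap between the two class
  scores) and `σ_ij = +1` for a Case call, `−1` for Control. The ensemble
  score is `E_i = Σ_j v_ij`.
- **ROC/Youden analysis**: Mann–Whitney AUC over the real samples'
  out-of-fold ensemble scores, decision cutoff `t*` maximizing the Youden
  index `J = sensitivity + specificity − 1`, confusion matrix and rates with
  binomial standard errors at `t*`.
- **Grid-search hyperparameter optimization** and **GA wrapper feature
  selection** (binary chromosomes, tournament selection, uniform crossover,
  elitism), toggled to form the four standard configurations (FO / noFS /
  noOpt / none).
- **Label-permutation overfitting check** (default n = 5): no permuted-label
  classifier should reach the 60% gate.
- A **synthetic-data generator** for wide-short two-class log-normal
  intensity tables with controllable effect size and known informative
  features, so the whole pipeline is testable without external downloads.

## Worked example

```r
library(dweml)

tab <- simulate_feature_table(synthetic_spec(seed = 7))   # 30/30 x 200, 10 informative
pre <- apply_recipe(tab, "autoscale")
aug <- balance_and_augment(pre, smote_config(target_total = 100, seed = 3))
model <- fit_ensemble(aug, run_config(cv_folds = 10, seed = 11))
model
```

```
Double-weighted ensemble
  base CV accuracies:  NB 0.99, GLM 0.98, LR 0.97, FLM 0.97, DL 0.96, DT 0.96, RF 1.00, GBT 0.98, SVM 0.95
  selected (gate 60%): 9/9
  AUC 1.000  cutoff 0.2723  J 1.000
performance: accuracy 100.0%  sens 100 +/- 0%  spec 100 +/- 0%  AUC 1.000
```

All nine families clear the gate on this strongly separated simulation and
the ensemble separates the 60 real samples perfectly; the confusion matrix,
sensitivity and specificity are computed on real samples only (the 40 SMOTE
rows train the models but are never scored). On null data
(`effect_size_sd = 0`) the same pipeline collapses to chance (AUC ≈ 0.5) and
the permutation check reports per-family accuracies near 50%.

A thin command-line front end over the same functions ships in
`inst/cli/dweml.R` (subcommands `simulate`, `train --all-configs`,
`predict`, `permute`).

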
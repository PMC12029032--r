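#' Double-weighted voting score of one classifier on one sample
#'
#' Each base classifier's vote is its prediction score `s` multiplied by its
#' cross-validation accuracy `a` and its per-sample classification confidence
#' `c` (the pre-score), signed +1 for a Case prediction and -1 for Control.
#' The double weighting downweights both globally weak classifiers (low `a`)
#' and individually hesitant predictions (low `c`).
#'
#' @param oof A data.frame with columns `predicted` (Case/Control), `score`
#'   and `confidence` — e.g. rows of a `base_report$oof`.
#' @param cv_accuracy The classifier's CV accuracy `a` in \[0, 1\].
#' @return Numeric vector of signed voting scores `v = sign * s * a * c`.
#' @export
vote_score <- function(oof, cv_accuracy) {
  s <- oof$score; c <- oof$confidence
  if (any(s < 0 | s > 1 | c < 0 | c > 1) ||
      cv_accuracy < 0 || cv_accuracy > 1)
    stop("score, confidence and cv_accuracy must lie in [0, 1]", call. = FALSE)
  sign <- ifelse(oof$predicted == "Case", 1, -1)
  sign * s * cv_accuracy * c
}

#' Out-of-fold ensemble scores for every sample
#'
#' The ensemble score of a sample is the sum of the voting scores of all
#' selected classifiers for that sample: `E = sum_j sign_j * s_j * a_j * c_j`.
#' `|E|` is bounded by the number of selected classifiers.
#'
#' @param selected_reports Non-empty list of gated-in `base_report`s covering
#'   the same samples.
#' @return data.frame: `sample_id`, `actual`, `synthetic`, `ensemble_score`.
#' @export
ensemble_scores <- function(selected_reports) {
  stopifnot(length(selected_reports) >= 1)
  ref <- selected_reports[[1]]$oof
  E <- rep(0, nrow(ref))
  for (r in selected_reports) {
    if (!identical(r$oof$sample_id, ref$sample_id))
      stop("internal error: OOF prediction coverage differs between classifiers",
           call. = FALSE)
    E <- E + vote_score(r$oof, r$cv_accuracy)
  }
  data.frame(sample_id = ref$sample_id, actual = ref$actual,
             synthetic = ref$synthetic, ensemble_score = E,
             stringsAsFactors = FALSE)
}

#' Ensemble score of a single sample
#'
#' @param sample_id Sample ID present in every selected report.
#' @param selected_reports List of gated-in `base_report`s.
#' @return The signed ensemble score `E`.
#' @export
ensemble_score <- function(sample_id, selected_reports) {
  sc <- ensemble_scores(selected_reports)
  i <- match(sample_id, sc$sample_id)
  if (is.na(i))
    stop("internal error: no out-of-fold prediction for sample '", sample_id,
         "'", call. = FALSE)
  sc$ensemble_score[i]
}

#' ROC curve of ensemble scores
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' scores plus -Inf/+Inf sentinels; a sample is called Case iff its score is
#' `>=` the threshold. The AUC uses the Mann-Whitney formulation (rank
#' statistic; tied pairs contribute 1/2), so it is exact under ties.
#'
#' @param scores Numeric ensemble scores of the real samples.
#' @param labels Case/Control labels of the same samples (both classes
#'   required).
#' @return A `roc_curve` object: data.frame `points` (threshold, tpr, fpr),
#'   `auc`, and after [youden_cutoff()] the chosen cutoff.
#' @export
roc_curve <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = c("Control", "Case"))
  if (anyNA(labels) || length(unique(labels)) < 2 || length(scores) != length(labels))
    stop("ROC needs scores for both Case and Control samples", call. = FALSE)
  n_case <- sum(labels == "Case"); n_ctrl <- sum(labels == "Control")
  su <- sort(unique(scores))
  thr <- c(-Inf, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2, Inf)
  tpr <- vapply(thr, function(t) mean(scores[labels == "Case"] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == "Control"] >= t), numeric(1))
  # Mann-Whitney AUC: average rank of Case scores (ties share ranks -> 1/2)
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[labels == "Case"]) - n_case * (n_case + 1) / 2) /
    (n_case * n_ctrl)
  structure(list(points = data.frame(threshold = thr, tpr = tpr, fpr = fpr),
                 auc = auc, n_case = n_case, n_control = n_ctrl),
            class = "roc_curve")
}

#' @export
#' @method print roc_curve
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC %.4f (%d Case vs %d Control, %d thresholds)\n",
              x$auc, x$n_case, x$n_control, nrow(x$points)))
  invisible(x)
}

#' Youden-optimal classification cutoff
#'
#' Picks the threshold maximizing the Youden index
#' `J = sensitivity + specificity - 1 = TPR - FPR` over the ROC's candidate
#' thresholds. Ties are broken toward higher sensitivity (TPR), then toward
#' the lower threshold.
#'
#' @param roc A [roc_curve()].
#' @return List with `cutoff` (threshold t*) and `j` (the attained J).
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  p <- roc$points
  j <- p$tpr - p$fpr
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[p$tpr[best] == max(p$tpr[best])]
  if (length(best) > 1) best <- best[which.min(p$threshold[best])]
  list(cutoff = p$threshold[best], j = j[best])
}

#' Confusion matrix and rates at a cutoff
#'
#' Calls a sample Case iff its ensemble score is `>=` the cutoff (the same
#' inclusive convention as the accuracy gate) and reports the confusion
#' counts, accuracy, and sensitivity/specificity each with the binomial Wald
#' standard error `sqrt(p (1 - p) / m)` on its own denominator (the "85
#' +/- 8%" convention). A zero denominator yields `NaN`, never 0.
#'
#' @param scores Ensemble scores of real samples.
#' @param labels Their Case/Control labels.
#' @param cutoff Decision threshold (finite, or a -Inf/+Inf sentinel).
#' @return A `performance_report` list: counts `tp/fp/tn/fn`, `accuracy`,
#'   `sensitivity` + `sensitivity_se`, `specificity` + `specificity_se`,
#'   `cutoff`, and slots `auc`/`youden_j` filled by [fit_ensemble()].
#' @export
evaluate <- function(scores, labels, cutoff) {
  labels <- factor(as.character(labels), levels = c("Control", "Case"))
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  called_case <- scores >= cutoff
  tp <- sum(called_case & labels == "Case")
  fp <- sum(called_case & labels == "Control")
  fn <- sum(!called_case & labels == "Case")
  tn <- sum(!called_case & labels == "Control")
  rate <- function(num, den) if (den == 0) NaN else num / den
  se <- function(p, m) if (m == 0 || is.nan(p)) NaN else sqrt(p * (1 - p) / m)
  sens <- rate(tp, tp + fn); spec <- rate(tn, tn + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 n = length(scores),
                 accuracy = rate(tp + tn, length(scores)),
                 sensitivity = sens, sensitivity_se = se(sens, tp + fn),
                 specificity = spec, specificity_se = se(spec, tn + fp),
                 cutoff = cutoff, auc = NA_real_, youden_j = NA_real_),
            class = "performance_report")
}

#' @export
#' @method print performance_report
print.performance_report <- function(x, ...) {
  cat(sprintf("performance: accuracy %.1f%%  sens %.0f +/- %.0f%%  spec %.0f +/- %.0f%%  AUC %s\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$sensitivity_se,
              100 * x$specificity, 100 * x$specificity_se,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Fit the double-weighted ensemble
#'
#' Orchestrates the core training stage on a pretreated, augmented table:
#' optional GA feature selection and per-family grid search (per the config
#' flags), stratified cross-validation of each classifier family, the
#' accuracy gate, out-of-fold ensemble scores, ROC analysis restricted to the
#' real (non-synthetic) samples, Youden-optimal cutoff and the confusion
#' matrix at that cutoff. Synthetic SMOTE rows take part in training and CV
#' but never in the reported metrics.
#'
#' @param table A pretreated, augmented [feature_table()].
#' @param config A [run_config()].
#' @return A `dweml_ensemble` with elements `reports` (all families),
#'   `selected`, `feature_ids`, `mask`, `cutoff`, `roc`, `performance`,
#'   `scores` (OOF ensemble scores), `optimization` (mask/specs/log when
#'   enabled), `config`, and `report` (the serializable result report).
#' @export
fit_ensemble <- function(table, config = run_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "run_config"))
  opt <- optimize_all(table, config)
  train_tab <- table[, opt$mask]
  reports <- lapply(config$families, function(fam)
    cross_validate(opt$specs[[fam]], train_tab, folds = config$cv_folds,
                   seed = config$seed))
  names(reports) <- config$families
  accs <- vapply(reports, `[[`, numeric(1), "cv_accuracy")
  selected <- select_classifiers(reports, config$accuracy_gate)
  if (length(selected) == 0)
    stop("no classifier passed the ", sprintf("%.0f%%", 100 * config$accuracy_gate),
         " accuracy gate; per-family CV accuracies: ",
         paste(sprintf("%s=%.3f", names(accs), accs), collapse = ", "),
         call. = FALSE)
  sc <- ensemble_scores(selected)
  real <- !sc$synthetic
  roc <- roc_curve(sc$ensemble_score[real], sc$actual[real])
  yj <- youden_cutoff(roc)
  perf <- evaluate(sc$ensemble_score[real], sc$actual[real], yj$cutoff)
  perf$auc <- roc$auc
  perf$youden_j <- yj$j
  model <- structure(
    list(reports = reports, selected = selected,
         feature_ids = colnames(train_tab$values), mask = opt$mask,
         cutoff = yj$cutoff, roc = roc, performance = perf, scores = sc,
         optimization = opt, config = config),
    class = "dweml_ensemble")
  model$report <- .build_report(model)
  model
}

.build_report <- function(model) {
  cfg <- model$config
  perf <- model$performance
  list(
    config = list(
      recipe = cfg$recipe,
      smote_target_total = cfg$smote_target_total,
      cv_folds = cfg$cv_folds,
      accuracy_gate = cfg$accuracy_gate,
      feature_selection = cfg$feature_selection,
      hyperparameter_optimization = cfg$hyperparameter_optimization,
      families = cfg$families,
      seed = cfg$seed),
    n_features_used = sum(model$mask),
    base_classifiers = lapply(model$reports, function(r)
      list(family = r$spec$family,
           params = r$spec$params,
           cv_accuracy = r$cv_accuracy,
           selected = r$cv_accuracy >= cfg$accuracy_gate)),
    n_selected = length(model$selected),
    ensemble = list(
      auc = perf$auc,
      youden_j = perf$youden_j,
      cutoff = perf$cutoff,
      confusion = list(tp = perf$tp, fp = perf$fp, tn = perf$tn, fn = perf$fn),
      n_real = perf$n,
      accuracy = perf$accuracy,
      sensitivity = perf$sensitivity,
      sensitivity_se = perf$sensitivity_se,
      specificity = perf$specificity,
      specificity_se = perf$specificity_se))
}

#' @export
#' @method print dweml_ensemble
print.dweml_ensemble <- function(x, ...) {
  accs <- vapply(x$reports, `[[`, numeric(1), "cv_accuracy")
  cat("Double-weighted ensemble\n")
  cat("  base CV accuracies: ",
      paste(sprintf("%s %.2f", names(accs), accs), collapse = ", "), "\n")
  cat(sprintf("  selected (gate %.0f%%): %d/%d\n",
              100 * x$config$accuracy_gate, length(x$selected), length(x$reports)))
  cat(sprintf("  AUC %.3f  cutoff %.4f  J %.3f\n",
              x$performance$auc, x$cutoff, x$performance$youden_j))
  print(x$performance)
  invisible(x)
}

#' Predict with a fitted ensemble
#'
#' Scores new samples with the refit base models of the selected classifiers,
#' weights each vote by the STORED cross-validation accuracy, sums to the
#' ensemble score and calls Case iff `E >=` the stored Youden cutoff.
#' Features are aligned by ID, not position; the input must be on the same
#' pretreatment scale as the training table.
#'
#' @param object A `dweml_ensemble`.
#' @param table A [feature_table()] or numeric matrix with named columns
#'   covering the model's features (extra features are ignored).
#' @param ... Unused.
#' @return data.frame: `sample_id`, `ensemble_score`, `predicted` — empty
#'   (zero rows) for empty input.
#' @export
predict.dweml_ensemble <- function(object, table, ...) {
  X <- if (inherits(table, "feature_table")) table$values else table
  stopifnot(is.matrix(X))
  missing <- setdiff(object$feature_ids, colnames(X))
  if (length(missing))
    stop("input lacks model feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- X[, object$feature_ids, drop = FALSE]
  E <- rep(0, nrow(X))
  if (nrow(X) > 0) {
    for (r in object$selected) {
      p <- make_classifier(r$spec)$predict_case(r$model, X)
      p <- pmin(pmax(p, 0), 1)
      sgn <- ifelse(p > 0.5, 1, -1)
      E <- E + sgn * pmax(p, 1 - p) * r$cv_accuracy * abs(2 * p - 1)
    }
  }
  data.frame(sample_id = if (nrow(X)) rownames(X) else character(0),
             ensemble_score = E,
             predicted = factor(ifelse(E >= object$cutoff, "Case", "Control"),
                                levels = c("Control", "Case")),
             stringsAsFactors = FALSE)
}

#' Export ROC points as CSV
#'
#' @param roc A [roc_curve()].
#' @param path Output CSV path (columns threshold, fpr, tpr).
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  utils::write.csv(roc$points[, c("threshold", "fpr", "tpr")], path,
                   row.names = FALSE)
  invisible(path)
}
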
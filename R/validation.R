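#' Label-permutation overfitting check
#'
#' Retrains the base classifier families on randomly permuted labels and
#' records every cross-validation accuracy. With the class structure
#' destroyed, no classifier should reach the accuracy gate; a gated-in
#' classifier under permuted labels is the signature of an overfitting
#' pipeline. By default labels are permuted over ALL rows of the augmented
#' table (real and synthetic), mirroring the training order of operations; a
#' permutation is a relabeling, so class counts are preserved exactly.
#'
#' Note that permuting after augmentation leaves the geometric link between a
#' synthetic point and its real parents intact while scrambling its label; a
#' stricter pre-augmentation permutation can be had by permuting labels on
#' the raw table and re-running the whole pipeline.
#'
#' @param table A pretreated, augmented [feature_table()].
#' @param config A [run_config()]; `n_permutations` (default 5),
#'   `accuracy_gate`, the CV scheme and the optimization flags are honored —
#'   if feature selection or grid search is enabled, each permutation re-runs
#'   it on the permuted labels.
#' @return A `permutation_report`: `n_permutations`, `accuracies` (matrix
#'   permutation x family), `max_accuracy` per permutation, `gate`, `pass`
#'   (no accuracy reached the gate in any permutation) and `seeds`.
#' @export
permutation_test <- function(table, config = run_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "run_config"))
  seeds <- vapply(seq_len(config$n_permutations), function(i)
    derive_seed(config$seed, "permutation", i), integer(1))
  acc <- matrix(NA_real_, config$n_permutations, length(config$families),
                dimnames = list(NULL, config$families))
  for (i in seq_len(config$n_permutations)) {
    set.seed(seeds[i])
    perm <- sample.int(n_samples(table))
    ptab <- feature_table(table$values,
                          as.character(table$labels)[perm],
                          synthetic = table$synthetic)
    pcfg <- config
    pcfg$seed <- seeds[i]
    opt <- optimize_all(ptab, pcfg)
    ptrain <- ptab[, opt$mask]
    for (fam in config$families)
      acc[i, fam] <- cross_validate(opt$specs[[fam]], ptrain,
                                    folds = config$cv_folds, seed = seeds[i],
                                    refit = FALSE)$cv_accuracy
  }
  structure(list(n_permutations = config$n_permutations,
                 accuracies = acc,
                 max_accuracy = apply(acc, 1, max),
                 gate = config$accuracy_gate,
                 pass = all(acc < config$accuracy_gate),
                 seeds = seeds),
            class = "permutation_report")
}

#' @export
#' @method print permutation_report
print.permutation_report <- function(x, ...) {
  cat(sprintf("permutation_report: %d permutations, gate %.0f%% -> %s\n",
              x$n_permutations, 100 * x$gate,
              if (x$pass) "PASS (no permuted model reached the gate)"
              else "FAIL (overfitting suspected)"))
  cat("  per-permutation max accuracy:",
      paste(sprintf("%.3f", x$max_accuracy), collapse = ", "), "\n")
  invisible(x)
}
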
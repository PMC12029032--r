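#' Run the full training pipeline on a raw feature table
#'
#' Pretreat, augment with SMOTE to the minimum cohort size, run the enabled
#' optimization stages, fit the double-weighted ensemble, and run the
#' label-permutation overfitting check. This is the programmatic equivalent
#' of the `train` CLI subcommand for one configuration.
#'
#' @param table A raw [feature_table()].
#' @param config A [run_config()].
#' @param permute Run the permutation check (default `TRUE`).
#' @return A `dweml_run`: list with `model` (the [fit_ensemble()] result),
#'   `permutation` (a `permutation_report` or `NULL`), `table` (the
#'   pretreated, augmented table) and `report` (serializable via
#'   [write_report()], with the permutation summary attached).
#' @export
run_dweml <- function(table, config = run_config(), permute = TRUE) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "run_config"))
  pre <- apply_recipe(table, config$recipe, config$log_offset_policy)
  aug <- balance_and_augment(pre, smote_config(
    target_total = config$smote_target_total,
    k_neighbors = config$k_neighbors,
    seed = derive_seed(config$seed, "smote"),
    balance_first = config$balance_first))
  model <- fit_ensemble(aug, config)
  perm <- NULL
  report <- model$report
  if (permute) {
    perm <- permutation_test(aug, config)
    report$permutation <- list(
      n_permutations = perm$n_permutations,
      gate = perm$gate,
      max_accuracy_per_permutation = unname(perm$max_accuracy),
      pass = perm$pass)
  }
  structure(list(model = model, permutation = perm, table = aug,
                 report = report),
            class = "dweml_run")
}

#' @export
#' @method print dweml_run
print.dweml_run <- function(x, ...) {
  print(x$model)
  if (!is.null(x$permutation)) print(x$permutation)
  invisible(x)
}

#' Train under the four standard configurations
#'
#' Runs the pipeline once per configuration: fully optimized (feature
#' selection + hyperparameter optimization, "FO"), without feature selection
#' ("noFS"), without hyperparameter optimization ("noOpt") and with neither
#' ("none").
#'
#' @param table A raw [feature_table()].
#' @param config Base [run_config()]; its FS/Opt flags are overridden per
#'   configuration.
#' @param permute Run the permutation check in each configuration.
#' @return Named list of four `dweml_run` objects (`FO`, `noFS`, `noOpt`,
#'   `none`).
#' @export
run_all_configs <- function(table, config = run_config(), permute = FALSE) {
  flags <- list(FO    = c(TRUE, TRUE),
                noFS  = c(FALSE, TRUE),
                noOpt = c(TRUE, FALSE),
                none  = c(FALSE, FALSE))
  lapply(flags, function(fl) {
    cfg <- config
    cfg$feature_selection <- fl[1]
    cfg$hyperparameter_optimization <- fl[2]
    run_dweml(table, cfg, permute = permute)
  })
}

#' Save / load a fitted run
#'
#' The fitted models of the base learners are binary R objects, so runs are
#' persisted with R's native serialization (format version 3), wrapped with a
#' schema version for forward compatibility.
#'
#' @param run A `dweml_run` or `dweml_ensemble`.
#' @param path Destination `.rds` path.
#' @export
save_model <- function(run, path) {
  saveRDS(list(format = "dweml-model", version = 1L, object = run), path,
          version = 3)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the stored object.
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "dweml-model"))
    stop("'", path, "' is not a dweml model archive", call. = FALSE)
  x$object
}
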
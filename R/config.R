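#' Run configuration
#'
#' Bundles every tunable of the pipeline: pretreatment recipe, SMOTE
#' augmentation, cross-validation, the accuracy gate, the optional
#' feature-selection and hyperparameter-optimization stages, and the
#' permutation check.
#'
#' @param recipe Character vector of pretreatment steps (see [apply_recipe()]).
#' @param log_offset_policy Zero handling for the log10 step.
#' @param smote_target_total Minimum cohort size after augmentation
#'   (default 100).
#' @param k_neighbors SMOTE neighborhood size (default 5).
#' @param balance_first Balance classes before growing the cohort.
#' @param cv_folds Number of stratified CV folds (default 10).
#' @param accuracy_gate CV-accuracy threshold, inclusive, for a base
#'   classifier to join the ensemble (default 0.60).
#' @param feature_selection Run GA wrapper feature selection.
#' @param hyperparameter_optimization Run per-family grid search.
#' @param families Classifier families to train (default all nine).
#' @param grids Per-family hyperparameter grids; `NULL` loads the packaged
#'   defaults ([default_grids()]).
#' @param ga A [ga_config()] for the feature-selection stage.
#' @param n_permutations Number of label permutations in the overfitting
#'   check (default 5).
#' @param seed Master seed; all stage seeds derive from it ([derive_seed()]).
#' @return A `run_config` list.
#' @export
run_config <- function(recipe = character(),
                       log_offset_policy = "error_on_nonpositive",
                       smote_target_total = 100,
                       k_neighbors = 5,
                       balance_first = TRUE,
                       cv_folds = 10,
                       accuracy_gate = 0.60,
                       feature_selection = FALSE,
                       hyperparameter_optimization = FALSE,
                       families = CLASSIFIER_FAMILIES,
                       grids = NULL,
                       ga = ga_config(),
                       n_permutations = 5,
                       seed = 1) {
  stopifnot(accuracy_gate > 0, accuracy_gate < 1,
            smote_target_total >= 2, cv_folds >= 2, n_permutations >= 1)
  stopifnot(all(families %in% CLASSIFIER_FAMILIES))
  structure(list(
    recipe = recipe,
    log_offset_policy = log_offset_policy,
    smote_target_total = as.integer(smote_target_total),
    k_neighbors = as.integer(k_neighbors),
    balance_first = isTRUE(balance_first),
    cv_folds = as.integer(cv_folds),
    accuracy_gate = accuracy_gate,
    feature_selection = isTRUE(feature_selection),
    hyperparameter_optimization = isTRUE(hyperparameter_optimization),
    families = families,
    grids = grids,
    ga = ga,
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed)),
    class = "run_config")
}

#' Genetic-algorithm feature-selection configuration
#'
#' Binary-chromosome GA with tournament selection (size 3), uniform
#' crossover, per-bit mutation and single-individual elitism; the all-ones
#' mask is seeded into the initial population so the search can never end
#' below the no-selection baseline. Fitness is a pure accuracy criterion
#' (accuracy weight 1.0).
#'
#' @param population_size Even number of chromosomes per generation.
#' @param max_generations Generation cap (the practical complexity bound).
#' @param time_limit_s Wall-clock limit in seconds; the search stops at the
#'   cap or the limit, whichever comes first. Results are fully
#'   deterministic per seed when the generation cap is reached first.
#' @param crossover_rate Probability a selected pair undergoes uniform
#'   crossover.
#' @param mutation_rate Per-bit flip probability; `NULL` (default) uses
#'   `1 / n_features`.
#' @param accuracy_weight Weight of accuracy in the fitness (fixed 1.0:
#'   pure-accuracy criterion; no parsimony pressure).
#' @param min_features Lower bound on selected features.
#' @param seed GA seed (default 1992).
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 50, max_generations = 40,
                      time_limit_s = 400, crossover_rate = 0.9,
                      mutation_rate = NULL, accuracy_weight = 1.0,
                      min_features = 1, seed = 1992) {
  stopifnot(population_size >= 2, population_size %% 2 == 0,
            max_generations >= 1, time_limit_s > 0,
            crossover_rate >= 0, crossover_rate <= 1,
            is.null(mutation_rate) || (mutation_rate >= 0 && mutation_rate <= 1),
            min_features >= 1)
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 time_limit_s = time_limit_s,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 accuracy_weight = accuracy_weight,
                 min_features = as.integer(min_features),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Packaged default hyperparameter grids
#'
#' Compact per-family search spaces (at most a couple of dozen points each)
#' shipped as an editable YAML file under `inst/extdata/default_grids.yaml`.
#'
#' @param path Optional path to an alternative grid file with the same schema
#'   (family -> parameter -> list of values).
#' @return Named list: family -> named list of parameter value vectors.
#' @export
default_grids <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_grids.yaml", package = "dweml",
                        mustWork = TRUE)
  grids <- yaml::read_yaml(path)
  bad <- setdiff(names(grids), CLASSIFIER_FAMILIES)
  if (length(bad))
    stop("grid file names unknown families: ", paste(bad, collapse = ", "),
         call. = FALSE)
  grids
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ga_raw <- raw$ga
  raw$ga <- NULL
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown run-config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- do.call(run_config, raw)
  if (!is.null(ga_raw)) cfg$ga <- do.call(ga_config, ga_raw)
  cfg
}
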
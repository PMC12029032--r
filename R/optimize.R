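#' Grid-search hyperparameter optimization for one family
#'
#' Evaluates every point of the Cartesian grid by stratified cross-validation
#' and returns the specification with the highest CV accuracy; ties are
#' broken by earliest grid order (row-major over `expand.grid` of the
#' parameters in the order listed). The full evaluation log is retained.
#'
#' @param family Classifier family code.
#' @param grid Named list: parameter -> vector of candidate values.
#' @param table A [feature_table()].
#' @param folds CV folds.
#' @param seed Seed shared across grid points, so every candidate sees the
#'   same fold assignment.
#' @param cap Maximum allowed grid size (default 512).
#' @return List: `spec` (winning [classifier_spec()]), `cv_accuracy`, and
#'   `log` (data.frame of every candidate and its accuracy).
#' @export
grid_search <- function(family, grid, table, folds = 10, seed = 1, cap = 512) {
  stopifnot(is.list(grid), length(grid) >= 1)
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(pts) > cap)
    stop("grid for ", family, " has ", nrow(pts), " points, above the cap of ",
         cap, "; use a coarser grid", call. = FALSE)
  acc <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    spec <- classifier_spec(family, as.list(pts[i, , drop = FALSE]))
    acc[i] <- cross_validate(spec, table, folds = folds, seed = seed,
                             refit = FALSE)$cv_accuracy
  }
  best <- which.max(acc)   # first maximum = earliest grid order
  log <- cbind(pts, cv_accuracy = acc)
  list(spec = classifier_spec(family, as.list(pts[best, , drop = FALSE])),
       cv_accuracy = acc[best], log = log)
}

# default GA fitness: 5-fold CV accuracy of a fast ridge-logistic probe
.probe_evaluator <- function(table, seed) {
  folds <- min(5, min(table(table$labels)))
  force(seed)
  function(mask) {
    sub <- table[, mask]
    cross_validate(classifier_spec("GLM"), sub, folds = folds, seed = seed,
                   refit = FALSE)$cv_accuracy
  }
}

#' Genetic-algorithm wrapper feature selection
#'
#' Binary-chromosome GA over feature masks: tournament selection of size 3,
#' uniform crossover, per-bit mutation and elitism of one. The all-ones mask
#' is seeded into the initial population, so the best-ever fitness can never
#' fall below the use-everything baseline, and elitism makes it non-
#' decreasing across generations. The search stops at the generation cap or
#' the wall-clock limit, whichever comes first; runs are fully deterministic
#' per seed when the cap binds first.
#'
#' @param table A [feature_table()] with at least 2 features.
#' @param evaluator Function mask -> fitness in \[0, 1\]; `NULL` uses the
#'   default probe (cross-validated accuracy of a ridge-logistic classifier
#'   on the masked features).
#' @param config A [ga_config()].
#' @return A `feature_mask`: list with `mask` (logical, one per feature),
#'   `fitness`, `generation_found`, `history` (best-ever fitness per
#'   generation) and `n_evaluations`.
#' @export
ga_feature_select <- function(table, evaluator = NULL, config = ga_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "ga_config"))
  p <- ncol(table$values)
  if (p < 2) stop("feature selection needs at least 2 features", call. = FALSE)
  if (is.null(evaluator))
    evaluator <- .probe_evaluator(table, derive_seed(config$seed, "ga-probe"))
  mrate <- if (is.null(config$mutation_rate)) 1 / p else config$mutation_rate
  t0 <- Sys.time()
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fitness_of <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- evaluator(mask)
    if (!is.finite(f))
      stop("GA evaluator returned non-finite fitness for mask with ",
           sum(mask), " features", call. = FALSE)
    n_eval <<- n_eval + 1L
    cache[[key]] <- f
    f
  }
  repair <- function(mask) {
    need <- config$min_features - sum(mask)
    if (need > 0) mask[sample(which(!mask), need)] <- TRUE
    mask
  }
  set.seed(config$seed)
  pop <- c(list(rep(TRUE, p)),
           replicate(config$population_size - 1,
                     repair(stats::runif(p) > 0.5), simplify = FALSE))
  best_mask <- NULL; best_fit <- -Inf; best_gen <- 0L
  history <- numeric(0)
  for (gen in seq_len(config$max_generations)) {
    fits <- vapply(pop, fitness_of, numeric(1))
    if (max(fits) > best_fit) {
      best_fit <- max(fits); best_mask <- pop[[which.max(fits)]]; best_gen <- gen
    }
    history <- c(history, best_fit)
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > config$time_limit_s)
      break
    if (gen == config$max_generations) break
    tournament <- function() {
      cand <- sample.int(length(pop), min(3, length(pop)))
      pop[[cand[which.max(fits[cand])]]]
    }
    nxt <- list(pop[[which.max(fits)]])   # elitism of 1
    while (length(nxt) < config$population_size) {
      p1 <- tournament(); p2 <- tournament()
      if (stats::runif(1) < config$crossover_rate) {
        swap <- stats::runif(p) < 0.5
        tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
      }
      for (child in list(p1, p2)) {
        if (length(nxt) >= config$population_size) break
        flip <- stats::runif(p) < mrate
        child <- xor(child, flip)
        nxt <- c(nxt, list(repair(child)))
      }
    }
    pop <- nxt
  }
  structure(list(mask = best_mask, fitness = best_fit,
                 generation_found = best_gen, history = history,
                 n_evaluations = n_eval),
            class = "feature_mask")
}

#' @export
#' @method print feature_mask
print.feature_mask <- function(x, ...) {
  cat(sprintf("feature_mask: %d/%d features, fitness %.3f (generation %d, %d evaluations)\n",
              sum(x$mask), length(x$mask), x$fitness, x$generation_found,
              x$n_evaluations))
  invisible(x)
}

#' Run the enabled optimization stages
#'
#' Applies GA feature selection first (one mask shared by all families), then
#' per-family grid search on the masked features; a disabled stage passes
#' through the identity (all features / the per-family default
#' specification).
#'
#' @param table A pretreated, augmented [feature_table()].
#' @param config A [run_config()].
#' @return List: `mask` (logical per feature), `specs` (named list of
#'   [classifier_spec()] per family), `log` (data.frame: stage, family,
#'   candidate, fitness) and `ga` (the `feature_mask`, or `NULL`).
#' @export
optimize_all <- function(table, config = run_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "run_config"))
  log <- data.frame(stage = character(0), family = character(0),
                    candidate = character(0), fitness = numeric(0),
                    stringsAsFactors = FALSE)
  ga <- NULL
  mask <- rep(TRUE, ncol(table$values))
  if (config$feature_selection) {
    ga <- ga_feature_select(table, config = config$ga)
    mask <- ga$mask
    log <- rbind(log, data.frame(
      stage = "feature_selection", family = "GA",
      candidate = sprintf("%d/%d features", sum(mask), length(mask)),
      fitness = ga$fitness, stringsAsFactors = FALSE))
  }
  specs <- lapply(config$families, default_spec)
  names(specs) <- config$families
  if (config$hyperparameter_optimization) {
    grids <- if (is.null(config$grids)) default_grids() else config$grids
    masked <- table[, mask]
    for (fam in config$families) {
      if (is.null(grids[[fam]])) next
      gs <- grid_search(fam, grids[[fam]], masked, folds = config$cv_folds,
                        seed = config$seed)
      specs[[fam]] <- gs$spec
      log <- rbind(log, data.frame(
        stage = "grid_search", family = fam,
        candidate = apply(gs$log[, setdiff(names(gs$log), "cv_accuracy"),
                                 drop = FALSE], 1,
                          function(r) paste(names(r), r, sep = "=",
                                            collapse = ",")),
        fitness = gs$log$cv_accuracy, stringsAsFactors = FALSE))
    }
  }
  list(mask = mask, specs = specs, log = log, ga = ga)
}
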
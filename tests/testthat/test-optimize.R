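xor_table <- function(n_per = 15, seed = 17) {
  set.seed(seed)
  centers <- expand.grid(x = c(-1, 1), y = c(-1, 1))
  v <- do.call(rbind, lapply(seq_len(4), function(i)
    cbind(rnorm(n_per, centers$x[i], 0.2), rnorm(n_per, centers$y[i], 0.2))))
  dimnames(v) <- list(paste0("S", seq_len(4 * n_per)), c("M1", "M2"))
  labels <- ifelse(centers$x[rep(1:4, each = n_per)] *
                     centers$y[rep(1:4, each = n_per)] > 0, "Case", "Control")
  feature_table(v, labels)
}

test_that("grid search returns the single point of a singleton grid", {
  tab <- separable_table(10, 5, seed = 1)
  gs <- grid_search("DT", list(maxdepth = 3), tab, folds = 5, seed = 1)
  expect_equal(gs$spec$params$maxdepth, 3)
  expect_equal(nrow(gs$log), 1)
})

test_that("grid search prefers the depth that can express XOR structure", {
  tab <- xor_table()
  gs <- grid_search("DT", list(maxdepth = c(1, 8)), tab, folds = 5, seed = 2)
  expect_equal(gs$spec$params$maxdepth, 8)
  # winner's accuracy dominates the evaluation log
  expect_true(all(gs$cv_accuracy >= gs$log$cv_accuracy))
  # determinism
  gs2 <- grid_search("DT", list(maxdepth = c(1, 8)), tab, folds = 5, seed = 2)
  expect_identical(gs$log, gs2$log)
})

test_that("oversized grids are rejected at the cap", {
  tab <- separable_table(8, 4, seed = 3)
  expect_error(grid_search("GBT", list(nrounds = 1:30, max_depth = 1:20),
                           tab, cap = 512), "coarser")
})

test_that("GA with no-op operators returns the seeded all-ones mask", {
  tab <- separable_table(10, 6, seed = 4)
  cfg <- ga_config(population_size = 2, max_generations = 2,
                   crossover_rate = 0, mutation_rate = 0, seed = 1)
  res <- ga_feature_select(tab, evaluator = function(m) mean(m), cfg)
  expect_true(all(res$mask))
  expect_equal(res$fitness, 1)
})

test_that("GA fitness is monotone non-decreasing and at least the baseline", {
  tab <- separable_table(10, 8, seed = 5)
  evaluator <- function(mask) {
    sub <- tab[, mask]
    cross_validate(classifier_spec("GLM"), sub, folds = 3, seed = 7,
                   refit = FALSE)$cv_accuracy
  }
  cfg <- ga_config(population_size = 8, max_generations = 4, seed = 2)
  res <- ga_feature_select(tab, evaluator, cfg)
  expect_true(all(diff(res$history) >= 0))
  expect_gte(res$fitness, evaluator(rep(TRUE, 8)))
  # deterministic when the generation cap binds
  res2 <- ga_feature_select(tab, evaluator, cfg)
  expect_identical(res$mask, res2$mask)
  expect_identical(res$fitness, res2$fitness)
})

test_that("GA recovers a strongly informative feature among noise", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    v <- matrix(rnorm(n * 12), n, 12,
                dimnames = list(paste0("S", 1:n), paste0("M", 1:12)))
    labels <- rep(c("Case", "Control"), each = n / 2)
    v[labels == "Case", 1] <- v[labels == "Case", 1] + 3
    tab <- feature_table(v, labels)
    cfg <- ga_config(population_size = 10, max_generations = 5, seed = s)
    res <- ga_feature_select(tab, config = cfg)
    hits <- hits + res$mask[1]
  }
  expect_gte(hits, 4)
})

test_that("GA errors on non-finite fitness", {
  tab <- separable_table(8, 4, seed = 6)
  expect_error(
    ga_feature_select(tab, evaluator = function(m) NaN,
                      ga_config(population_size = 2, max_generations = 1)),
    "non-finite")
})

test_that("masked-out features are truly inert in training", {
  tab <- separable_table(12, 6, delta = 5, seed = 8)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  sub <- tab[, mask]
  r1 <- cross_validate(classifier_spec("DT"), sub, folds = 4, seed = 3)
  scrambled <- tab
  set.seed(99)
  scrambled$values[, !mask] <- scrambled$values[sample(nrow(tab$values)), !mask]
  r2 <- cross_validate(classifier_spec("DT"), scrambled[, mask], folds = 4,
                       seed = 3)
  expect_identical(r1$oof, r2$oof)
})

test_that("optimize_all passes through identities when stages are disabled", {
  tab <- separable_table(10, 5, seed = 9)
  cfg <- run_config(feature_selection = FALSE,
                    hyperparameter_optimization = FALSE)
  opt <- optimize_all(tab, cfg)
  expect_true(all(opt$mask))
  expect_equal(length(opt$specs), 9)
  expect_true(all(vapply(opt$specs, function(s) length(s$params) == 0,
                         logical(1))))
  expect_equal(nrow(opt$log), 0)
})
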
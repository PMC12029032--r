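test_that("vote_score multiplies score, accuracy and confidence with the class sign", {
  oof <- data.frame(predicted = factor(c("Case", "Control", "Case"),
                                       levels = c("Control", "Case")),
                    score = c(0.9, 0.9, 0.7), confidence = c(0.7, 0.7, 0))
  v <- vote_score(oof, 0.8)
  expect_equal(v, c(0.504, -0.504, 0))
  expect_error(vote_score(data.frame(predicted = "Case", score = 1.2,
                                     confidence = 0.5), 0.9),
               "\\[0, 1\\]")
})

test_that("ensemble score sums votes and respects its bound", {
  r1 <- fake_report("NB", 1, "Case", 0.5, 1)        # +0.5
  r2 <- fake_report("DT", 1, "Control", 0.2, 1)     # -0.2
  r3 <- fake_report("RF", 1, "Case", 0.1, 1)        # +0.1
  expect_equal(ensemble_score("S1", list(r1)), 0.5)
  expect_equal(ensemble_score("S1", list(r1, r2, r3)), 0.4)

  perfect <- lapply(1:5, function(i) fake_report("NB", 1, "Case", 1, 1))
  expect_equal(ensemble_score("S1", perfect), 5)
})

test_that("roc_curve handles separation, ties and mixed orderings", {
  roc <- roc_curve(c(0.8, 0.9, 0.1, 0.2),
                   c("Case", "Case", "Control", "Control"))
  expect_equal(roc$auc, 1)
  expect_true(all(diff(roc$points$tpr) <= 0))
  expect_true(all(diff(roc$points$fpr) <= 0))

  expect_equal(roc_curve(rep(0.3, 6), rep(c("Case", "Control"), 3))$auc, 0.5)

  # brute-force pair counting: 3 wins of 4 pairs
  expect_equal(roc_curve(c(0.9, 0.2, 0.8, 0.1),
                         c("Case", "Case", "Control", "Control"))$auc, 0.75)

  expect_error(roc_curve(1:3, rep("Case", 3)), "both")
})

test_that("AUC agrees with pROC on a mixed-tie example", {
  skip_if_not_installed("pROC")
  set.seed(14)
  sc <- round(rnorm(40), 1)   # rounding forces ties
  lab <- sample(rep(c("Case", "Control"), 20))
  ours <- roc_curve(sc, lab)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(response = lab, predictor = sc, levels = c("Control", "Case"),
              direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("youden_cutoff maximizes TPR - FPR with documented tie-breaks", {
  roc <- roc_curve(c(0.8, 0.9, 0.1, 0.2),
                   c("Case", "Case", "Control", "Control"))
  yj <- youden_cutoff(roc)
  expect_equal(yj$cutoff, 0.5)   # midpoint of 0.2 and 0.8
  expect_equal(yj$j, 1)

  # anti-separated scores: no threshold beats the sentinels, J* = 0
  anti <- roc_curve(c(0.1, 0.2, 0.8, 0.9),
                    c("Case", "Case", "Control", "Control"))
  expect_equal(youden_cutoff(anti)$j, 0)
})

test_that("evaluate reproduces a hand confusion matrix and Wald SEs", {
  sc <- c(1, -1, -1, -1)
  lab <- c("Case", "Case", "Control", "Control")
  perf <- evaluate(sc, lab, 0)
  expect_equal(unlist(perf[c("tp", "fn", "tn", "fp")]),
               c(tp = 1, fn = 1, tn = 2, fp = 0))
  expect_equal(perf$accuracy, 0.75)
  expect_equal(perf$sensitivity, 0.5)
  expect_equal(perf$specificity, 1.0)

  expect_equal(sqrt(0.85 * 0.15 / 20), 0.0798, tolerance = 1e-3)
  p20 <- evaluate(c(rep(1, 17), rep(-1, 3)), rep("Case", 20), 0)
  # all-Case input: specificity denominator is zero -> NaN, never 0
  expect_true(is.nan(p20$specificity))
  expect_equal(p20$sensitivity, 0.85)
  expect_equal(p20$sensitivity_se, sqrt(0.85 * 0.15 / 20))
})

test_that("swapping Case and Control negates every ensemble score exactly", {
  set.seed(23)
  n <- 30
  reports <- lapply(c("NB", "DT", "RF"), function(f)
    fake_report(f, runif(1), sample(c("Case", "Control"), n, TRUE),
                runif(n, 0.5, 1), runif(n)))
  E <- ensemble_scores(reports)$ensemble_score
  flipped <- lapply(reports, function(r) {
    r$oof$predicted <- factor(ifelse(r$oof$predicted == "Case",
                                     "Control", "Case"),
                              levels = c("Control", "Case"))
    r$oof$actual <- factor(ifelse(r$oof$actual == "Case", "Control", "Case"),
                           levels = c("Control", "Case"))
    r
  })
  expect_identical(ensemble_scores(flipped)$ensemble_score, -E)
  # Youden J* is invariant under the simultaneous swap
  lab <- ensemble_scores(reports)$actual
  j1 <- youden_cutoff(roc_curve(E, lab))$j
  lab2 <- factor(ifelse(lab == "Case", "Control", "Case"),
                 levels = c("Control", "Case"))
  j2 <- youden_cutoff(roc_curve(-E, lab2))$j
  expect_equal(j1, j2, tolerance = 1e-12)
})

test_that("sub-gate classifiers never contribute to the ensemble score", {
  set.seed(29)
  n <- 12
  strong <- fake_report("RF", 0.9, sample(c("Case", "Control"), n, TRUE),
                        runif(n, 0.5, 1), runif(n))
  weak <- fake_report("DT", 0.4, sample(c("Case", "Control"), n, TRUE),
                      runif(n, 0.5, 1), runif(n))
  sel <- select_classifiers(list(strong, weak), 0.6)
  expect_length(sel, 1)
  expect_identical(ensemble_scores(sel)$ensemble_score,
                   ensemble_scores(list(strong))$ensemble_score)
})

test_that("fit_ensemble reports an informative error when nothing passes the gate", {
  set.seed(41)
  v <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(paste0("S", 1:30), paste0("M", 1:8)))
  tab <- feature_table(v, sample(rep(c("Case", "Control"), 15)))
  cfg <- run_config(cv_folds = 5, accuracy_gate = 0.99,
                    families = c("GLM", "DT"), seed = 2)
  expect_error(fit_ensemble(tab, cfg), "no classifier passed")
  expect_error(fit_ensemble(tab, cfg), "GLM=")
})

test_that("fit_ensemble and predict are deterministic and self-consistent", {
  tab <- separable_table(15, 12, delta = 4, seed = 10)
  cfg <- run_config(cv_folds = 5, families = c("GLM", "DT", "RF"), seed = 6)
  m1 <- fit_ensemble(tab, cfg)
  m2 <- fit_ensemble(tab, cfg)
  expect_identical(m1$report, m2$report)
  expect_gte(m1$performance$auc, 0.95)

  pred <- predict(m1, tab)
  expect_identical(pred, predict(m1, tab))
  expect_equal(nrow(pred), 30)
  # prototype Case sample scores as Case on separated data
  expect_equal(as.character(pred$predicted[1]), "Case")

  # feature alignment is by ID, not position
  shuffled <- tab$values[, rev(seq_len(ncol(tab$values)))]
  expect_identical(predict(m1, shuffled)$ensemble_score, pred$ensemble_score)

  empty <- tab$values[integer(0), , drop = FALSE]
  expect_equal(nrow(predict(m1, empty)), 0)
  expect_error(predict(m1, tab$values[, 1:3]), "M4")
})
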
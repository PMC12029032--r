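test_that("specs validate family and hyperparameter names", {
  expect_error(classifier_spec("XGB"), "NB, GLM, LR, FLM, DL, DT, RF, GBT, SVM")
  expect_error(classifier_spec("DT", list(depth = 3)), "maxdepth")
  s <- classifier_spec("DT", list(maxdepth = 3))
  expect_s3_class(s, "classifier_spec")
})

test_that("every family fits and returns complementary scores on a toy table", {
  tab <- separable_table(10, 6, delta = 4, seed = 3)
  for (fam in CLASSIFIER_FAMILIES) {
    clf <- make_classifier(default_spec(fam))
    m <- clf$fit(tab$values, tab$labels, seed = 99)
    p <- clf$predict_case(m, tab$values[1:5, , drop = FALSE])
    expect_length(p, 5)
    expect_true(all(is.finite(p) & p >= 0 & p <= 1), info = fam)
  }
  # calibrated margin family: explicit two-class probabilities sum to 1
  clf <- make_classifier(default_spec("SVM"))
  m <- clf$fit(tab$values, tab$labels, seed = 1)
  pr <- attr(predict(m, tab$values, probability = TRUE), "probabilities")
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-9)
})

test_that("cross_validate covers every sample once and pools fold accuracies", {
  tab <- separable_table(15, 8, delta = 3, seed = 5)
  rep <- cross_validate(classifier_spec("DT"), tab, folds = 5, seed = 2)
  expect_setequal(rep$oof$sample_id, rownames(tab$values))
  expect_false(anyDuplicated(rep$oof$sample_id) > 0)
  # pooled OOF accuracy == fold-size-weighted mean of fold accuracies
  expect_equal(rep$cv_accuracy,
               sum(rep$fold_accuracy * rep$fold_sizes) / sum(rep$fold_sizes),
               tolerance = 1e-12)
  # confidence/score relation for complementary two-class scores
  expect_true(all(rep$oof$score >= 0.5 - 1e-12))
  expect_equal(rep$oof$confidence, abs(2 * rep$oof$p_case - 1))
})

test_that("cross_validate is deterministic and learns separable data", {
  tab <- separable_table(20, 10, delta = 6, seed = 7)
  a <- cross_validate(classifier_spec("RF"), tab, folds = 5, seed = 3)
  b <- cross_validate(classifier_spec("RF"), tab, folds = 5, seed = 3)
  expect_identical(a$oof, b$oof)
  expect_identical(a$cv_accuracy, b$cv_accuracy)
  expect_gte(a$cv_accuracy, 0.95)
})

test_that("noise data with permuted labels stays near chance", {
  set.seed(31)
  v <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(paste0("S", 1:40), paste0("M", 1:12)))
  tab <- feature_table(v, sample(rep(c("Case", "Control"), 20)))
  for (fam in c("GLM", "DT", "RF")) {
    acc <- cross_validate(classifier_spec(fam), tab, folds = 5, seed = 4)$cv_accuracy
    expect_gte(acc, 0.2)
    expect_lte(acc, 0.8)
  }
})

test_that("class smaller than fold count is rejected with guidance", {
  tab <- separable_table(4, 5, seed = 9)
  expect_error(cross_validate(classifier_spec("DT"), tab, folds = 10),
               "smaller number of folds")
})

test_that("the accuracy gate is inclusive and monotone", {
  reports <- lapply(c(0.59, 0.60, 0.85), function(a)
    fake_report("DT", a, "Case", 1, 1))
  expect_length(select_classifiers(reports, 0.60), 2)
  expect_length(select_classifiers(reports, 0.001), 3)
  expect_length(select_classifiers(reports, 0.99), 0)
  gates <- c(0.1, 0.3, 0.5, 0.6, 0.7, 0.9)
  sizes <- vapply(gates, function(g) length(select_classifiers(reports, g)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})
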
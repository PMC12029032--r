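#' The nine base classifier families
#'
#' Family codes trained by the ensemble: Gaussian naive Bayes (NB), ridge
#' logistic regression (GLM), lasso logistic regression (LR), calibrated
#' linear large-margin classifier (FLM), small feed-forward network (DL),
#' decision tree (DT), random forest (RF), gradient-boosted trees (GBT) and
#' calibrated RBF-kernel SVM (SVM).
#' @export
CLASSIFIER_FAMILIES <- c("NB", "GLM", "LR", "FLM", "DL", "DT", "RF", "GBT", "SVM")

.VALID_PARAMS <- list(
  NB  = "laplace",
  GLM = "lambda",
  LR  = "lambda",
  FLM = "cost",
  DL  = c("size", "decay", "maxit"),
  DT  = c("maxdepth", "cp", "minsplit"),
  RF  = c("num_trees", "mtry_frac", "min_node_size"),
  GBT = c("nrounds", "max_depth", "eta"),
  SVM = c("cost", "gamma_frac"))

#' Specify a base classifier
#'
#' The ensemble draws on nine classifier families: Gaussian naive Bayes (NB),
#' ridge-penalized logistic regression (GLM), lasso-penalized logistic
#' regression (LR), a linear large-margin classifier with Platt-calibrated
#' scores (FLM), a small feed-forward neural network (DL), a decision tree
#' (DT), a probability random forest (RF), gradient-boosted trees (GBT) and an
#' RBF-kernel support vector machine with calibrated scores (SVM).
#'
#' @param family One of `r paste(CLASSIFIER_FAMILIES, collapse = ", ")`.
#' @param params Named list of hyperparameters; valid names depend on the
#'   family (see the packaged `default_grids.yaml` for the search spaces).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(family, params = list()) {
  if (!is.character(family) || length(family) != 1 ||
      !family %in% CLASSIFIER_FAMILIES)
    stop("unknown classifier family '", paste(family, collapse = ","),
         "'; valid families: ", paste(CLASSIFIER_FAMILIES, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(names(params), .VALID_PARAMS[[family]])
  if (length(bad))
    stop("invalid hyperparameter(s) for ", family, ": ",
         paste(bad, collapse = ", "), "; valid: ",
         paste(.VALID_PARAMS[[family]], collapse = ", "), call. = FALSE)
  structure(list(family = family, params = params), class = "classifier_spec")
}

#' @export
#' @method print classifier_spec
print.classifier_spec <- function(x, ...) {
  p <- if (length(x$params))
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  else "defaults"
  cat(sprintf("classifier_spec: %s (%s)\n", x$family, p))
  invisible(x)
}

#' Default specification for a classifier family
#' @param family Family code.
#' @return A [classifier_spec()] with the package's default hyperparameters.
#' @export
default_spec <- function(family) classifier_spec(family)

.param <- function(spec, name, default) {
  v <- spec$params[[name]]
  if (is.null(v)) default else v
}

#' Build a trainable classifier from a specification
#'
#' Returns a handle with `fit(X, y, seed)` and `predict_case(model, X)`
#' where `X` is a numeric matrix, `y` a Control/Case factor, and the returned
#' score is P(Case) in \[0, 1\] (the two class-membership scores sum to 1).
#' Margin-based families (FLM, SVM) are Platt-calibrated within the training
#' data so their scores live on the same \[0, 1\] scale.
#'
#' @param spec A [classifier_spec()].
#' @return A list with elements `spec`, `fit` and `predict_case`.
#' @export
make_classifier <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  f <- switch(spec$family,
    NB = list(
      fit = function(X, y, seed) {
        # guard: Gaussian NB breaks on zero within-class variance
        keep <- apply(X, 2, function(col)
          min(tapply(col, y, stats::sd)) > 0)
        if (!any(keep)) stop("NB: no feature has positive within-class variance",
                             call. = FALSE)
        df <- as.data.frame(X[, keep, drop = FALSE])
        names(df) <- paste0("F", which(keep))
        m <- e1071::naiveBayes(df, y, laplace = .param(spec, "laplace", 0))
        list(model = m, keep = keep)
      },
      predict_case = function(m, X) {
        df <- as.data.frame(X[, m$keep, drop = FALSE])
        names(df) <- paste0("F", which(m$keep))
        predict(m$model, df, type = "raw")[, "Case"]
      }),
    GLM = .glmnet_family(spec, alpha = 0),
    LR  = .glmnet_family(spec, alpha = 1),
    FLM = .svm_family(spec, kernel = "linear"),
    DL = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        nnet::nnet(X, as.numeric(y == "Case"),
                   size = .param(spec, "size", 5),
                   decay = .param(spec, "decay", 0.01),
                   maxit = .param(spec, "maxit", 80),
                   entropy = TRUE, trace = FALSE,
                   MaxNWts = 100000)
      },
      predict_case = function(m, X) as.numeric(predict(m, X))),
    DT = list(
      fit = function(X, y, seed) {
        df <- as.data.frame(X); names(df) <- paste0("F", seq_len(ncol(X)))
        df$.y <- y
        rpart::rpart(.y ~ ., df, method = "class",
                     control = rpart::rpart.control(
                       maxdepth = .param(spec, "maxdepth", 8),
                       cp = .param(spec, "cp", 0.01),
                       minsplit = .param(spec, "minsplit", 5),
                       xval = 0))
      },
      predict_case = function(m, X) {
        df <- as.data.frame(X); names(df) <- paste0("F", seq_len(ncol(X)))
        predict(m, df, type = "prob")[, "Case"]
      }),
    RF = list(
      fit = function(X, y, seed) {
        mtry_frac <- .param(spec, "mtry_frac", NULL)
        ranger::ranger(
          x = X, y = y, probability = TRUE,
          num.trees = .param(spec, "num_trees", 500),
          mtry = if (is.null(mtry_frac)) NULL
                 else max(1L, floor(mtry_frac * ncol(X))),
          min.node.size = .param(spec, "min_node_size", 10),
          seed = seed, num.threads = 1)
      },
      predict_case = function(m, X)
        predict(m, X, num.threads = 1)$predictions[, "Case"]),
    GBT = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        dtr <- xgboost::xgb.DMatrix(X, label = as.numeric(y == "Case"))
        xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        max_depth = .param(spec, "max_depth", 3),
                        eta = .param(spec, "eta", 0.3),
                        nthread = 1),
          dtr, nrounds = .param(spec, "nrounds", 100), verbose = 0)
      },
      predict_case = function(m, X)
        predict(m, xgboost::xgb.DMatrix(X))),
    SVM = .svm_family(spec, kernel = "radial"))
  c(list(spec = spec), f)
}

.glmnet_family <- function(spec, alpha) {
  # glmnet requires >= 2 columns; pad single-feature inputs with a zero column
  pad <- function(X) if (ncol(X) < 2) cbind(X, .pad = 0) else X
  list(
    fit = function(X, y, seed) {
      # muffle glmnet's small-class advisory; tiny CV folds are expected here
      withCallingHandlers(
        glmnet::glmnet(pad(X), y, family = "binomial", alpha = alpha),
        warning = function(w) {
          if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    },
    predict_case = function(m, X)
      as.numeric(predict(m, pad(X), s = .param(spec, "lambda", 0.05),
                         type = "response")))
}

.svm_family <- function(spec, kernel) {
  list(
    fit = function(X, y, seed) {
      set.seed(seed)   # Platt calibration uses an internal CV
      gamma_frac <- .param(spec, "gamma_frac", 1)
      e1071::svm(X, y, kernel = kernel,
                 cost = .param(spec, "cost", 1),
                 gamma = gamma_frac / ncol(X),
                 probability = TRUE, scale = FALSE)
    },
    predict_case = function(m, X) {
      attr(predict(m, X, probability = TRUE), "probabilities")[, "Case"]
    })
}

#' Stratified cross-validation of one base classifier
#'
#' Runs stratified k-fold cross-validation over ALL rows of the (pretreated,
#' augmented) table. For each held-out sample the predicted class (Case iff
#' P(Case) > 0.5; an exact tie predicts Control), the prediction score
#' `s = max(P(Case), P(Control))` and the classification confidence
#' `c = |P(Case) - P(Control)|` (the distance from the classification margin)
#' are recorded. The CV accuracy is the pooled out-of-fold accuracy. The
#' model is refit on the full table for deployment unless `refit = FALSE`.
#'
#' @param spec A [classifier_spec()].
#' @param table A [feature_table()].
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed; fold assignment and every fit derive their own
#'   seeds from it, so results are reproducible per family.
#' @param refit Refit on the full table for later prediction (default `TRUE`).
#' @return A `base_report`: list with `spec`, `cv_accuracy`, `fold_accuracy`,
#'   `oof` (data.frame: sample_id, fold, actual, predicted, p_case, score,
#'   confidence, synthetic), and `model` (`NULL` when `refit = FALSE`).
#' @export
cross_validate <- function(spec, table, folds = 10, seed = 1, refit = TRUE) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(table, "feature_table"))
  y <- table$labels
  counts <- table(y)
  if (any(counts < folds))
    stop("smallest class has ", min(counts), " samples, fewer than folds = ",
         folds, "; use a smaller number of folds", call. = FALSE)
  n <- nrow(table$values)
  fold <- integer(n)
  set.seed(derive_seed(seed, "folds", folds))
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  clf <- make_classifier(spec)
  p_case <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    hold <- fold == f
    set.seed(derive_seed(seed, "fit", spec$family, f))
    m <- clf$fit(table$values[!hold, , drop = FALSE], y[!hold],
                 derive_seed(seed, "fit", spec$family, f))
    p_case[hold] <- clf$predict_case(m, table$values[hold, , drop = FALSE])
  }
  if (any(!is.finite(p_case)))
    stop(spec$family, ": non-finite class-membership scores produced",
         call. = FALSE)
  p_case <- pmin(pmax(p_case, 0), 1)
  predicted <- factor(ifelse(p_case > 0.5, "Case", "Control"),
                      levels = c("Control", "Case"))
  oof <- data.frame(
    sample_id = rownames(table$values),
    fold = fold,
    actual = y,
    predicted = predicted,
    p_case = p_case,
    score = pmax(p_case, 1 - p_case),
    confidence = abs(2 * p_case - 1),
    synthetic = table$synthetic,
    stringsAsFactors = FALSE)
  model <- NULL
  if (refit) {
    set.seed(derive_seed(seed, "refit", spec$family))
    model <- clf$fit(table$values, y, derive_seed(seed, "refit", spec$family))
  }
  structure(
    list(spec = spec,
         cv_accuracy = mean(predicted == y),
         fold_accuracy = vapply(seq_len(folds), function(f)
           mean((predicted == y)[fold == f]), numeric(1)),
         fold_sizes = tabulate(fold, folds),
         oof = oof,
         model = model,
         seed = seed),
    class = "base_report")
}

#' @export
#' @method print base_report
print.base_report <- function(x, ...) {
  cat(sprintf("base_report: %s  CV accuracy %.3f over %d folds\n",
              x$spec$family, x$cv_accuracy, length(x$fold_accuracy)))
  invisible(x)
}

#' Apply the accuracy gate to base classifier reports
#'
#' Only base classifiers whose cross-validation accuracy reaches the gate
#' (default 60%, inclusive) join the ensemble; input order is preserved and
#' an empty selection is a legitimate result handled by the caller.
#'
#' @param reports List of `base_report` objects.
#' @param gate Accuracy threshold in (0, 1).
#' @return The sub-list with `cv_accuracy >= gate`.
#' @export
select_classifiers <- function(reports, gate = 0.60) {
  stopifnot(length(reports) >= 1, gate > 0, gate < 1)
  reports[vapply(reports, function(r) r$cv_accuracy >= gate, logical(1))]
}
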
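# Fixtures are built in code; nothing is read from disk.

# tiny deterministic positive table: n samples, p features, balanced labels
tiny_table <- function(n = 6, p = 4, seed = 42) {
  set.seed(seed)
  v <- matrix(10^stats::rnorm(n * p, 3, 0.3), n, p,
              dimnames = list(paste0("S", seq_len(n)), paste0("M", seq_len(p))))
  feature_table(v, rep(c("Case", "Control"), length.out = n))
}

# two well-separated Gaussian classes (autoscaled-like values)
separable_table <- function(n_per = 20, p = 10, delta = 6, seed = 1) {
  set.seed(seed)
  v <- rbind(matrix(stats::rnorm(n_per * p, delta / 2), n_per, p),
             matrix(stats::rnorm(n_per * p, -delta / 2), n_per, p))
  dimnames(v) <- list(paste0("S", seq_len(2 * n_per)), paste0("M", seq_len(p)))
  feature_table(v, rep(c("Case", "Control"), each = n_per))
}

# fabricate a base_report with given accuracy and per-sample OOF votes
fake_report <- function(family, cv_accuracy, predicted, score, confidence,
                        actual = NULL, synthetic = NULL) {
  n <- length(predicted)
  if (is.null(actual)) actual <- predicted
  if (is.null(synthetic)) synthetic <- rep(FALSE, n)
  structure(list(
    spec = classifier_spec(family),
    cv_accuracy = cv_accuracy,
    oof = data.frame(
      sample_id = paste0("S", seq_len(n)),
      predicted = factor(predicted, levels = c("Control", "Case")),
      score = score, confidence = confidence,
      actual = factor(actual, levels = c("Control", "Case")),
      synthetic = synthetic, stringsAsFactors = FALSE),
    model = NULL), class = "base_report")
}

# exhaustive-scan Youden oracle: J is piecewise constant and changes only at
# observed scores, so scanning scores plus sentinels covers all thresholds
youden_oracle <- function(scores, labels) {
  thr <- c(-Inf, sort(unique(scores)), Inf)
  j <- vapply(thr, function(t)
    mean(scores[labels == "Case"] >= t) - mean(scores[labels == "Control"] >= t),
    numeric(1))
  max(j)
}

# Mann-Whitney AUC oracle by explicit pair counting (ties count 1/2)
auc_oracle <- function(scores, labels) {
  ca <- scores[labels == "Case"]; co <- scores[labels == "Control"]
  wins <- 0
  for (x in ca) wins <- wins + sum(x > co) + 0.5 * sum(x == co)
  wins / (length(ca) * length(co))
}
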
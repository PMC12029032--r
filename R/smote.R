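#' SMOTE configuration
#'
#' @param target_total Minimum total cohort size after augmentation. The
#'   ensemble requires at least 100 samples to train, so small studies are
#'   grown to this size with synthetic points.
#' @param k_neighbors Number of same-class nearest neighbors considered when
#'   interpolating (clipped, with a warning, when a class is smaller).
#' @param seed Integer seed controlling base-row/neighbor/interpolation draws.
#' @param balance_first If `TRUE` (default) the minority class is first grown
#'   to the majority size, then both classes grow equally to reach
#'   `target_total` — the imbalance check applied alongside the size minimum.
#' @return A `smote_config` list.
#' @export
smote_config <- function(target_total = 100, k_neighbors = 5, seed = 1,
                         balance_first = TRUE) {
  stopifnot(target_total >= 2, k_neighbors >= 1)
  structure(list(target_total = as.integer(target_total),
                 k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed),
                 balance_first = isTRUE(balance_first)),
            class = "smote_config")
}

#' Generate SMOTE points within one class
#'
#' Each synthetic row is `x + u * (x_nn - x)` where `x` is a real row of the
#' class (chosen cyclically so coverage is even), `x_nn` is one of its `k`
#' Euclidean nearest same-class neighbors (chosen uniformly), and
#' `u ~ Uniform(0, 1)`. Deterministic given `seed`.
#'
#' @param class_matrix Numeric matrix of the real rows of one class (>= 2).
#' @param n_new Number of synthetic rows to generate.
#' @param k Number of nearest neighbors; clipped to `nrow - 1` with a warning.
#' @param seed Integer seed.
#' @return A matrix with `n_new` rows in the same feature space.
#' @export
smote_points <- function(class_matrix, n_new, k = 5, seed = 1) {
  if (!is.matrix(class_matrix) || nrow(class_matrix) < 2)
    stop("SMOTE needs at least 2 real samples in the class", call. = FALSE)
  n <- nrow(class_matrix)
  if (k > n - 1) {
    warning("k_neighbors = ", k, " clipped to ", n - 1, " (class has ", n, " rows)",
            call. = FALSE)
    k <- n - 1
  }
  if (n_new == 0)
    return(matrix(numeric(0), 0, ncol(class_matrix),
                  dimnames = list(NULL, colnames(class_matrix))))
  d <- as.matrix(stats::dist(class_matrix))
  diag(d) <- Inf
  # k nearest same-class neighbors of each real row (ties by index order)
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) nn[i, ] <- order(d[i, ])[seq_len(k)]
  set.seed(seed)
  base <- ((seq_len(n_new) - 1L) %% n) + 1L
  pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  out <- class_matrix[base, , drop = FALSE] +
    u * (class_matrix[pick, , drop = FALSE] - class_matrix[base, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Balance classes and grow the cohort with SMOTE
#'
#' Two-phase policy: (1) if `balance_first`, the minority class is upsampled
#' to the majority size; (2) both classes are then upsampled equally (an odd
#' deficit gives the extra sample to Case) until the total reaches
#' `target_total`. An already balanced cohort of sufficient size is returned
#' unchanged. All interpolation uses the real rows of a class as base and
#' neighbor points, so every synthetic sample lies on a segment between two
#' real same-class samples; real rows are never modified.
#'
#' @param table A [feature_table()] with both classes present (>= 2 real
#'   samples each).
#' @param config A [smote_config()].
#' @return The augmented table; new rows carry `synthetic = TRUE` and IDs of
#'   the form `SMOTE_<class>_<i>`.
#' @export
balance_and_augment <- function(table, config = smote_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "smote_config"))
  real <- !table$synthetic
  counts <- table(factor(as.character(table$labels)[real], c("Control", "Case")))
  if (any(counts < 2))
    stop("each class needs at least 2 real samples for SMOTE; have Control = ",
         counts[["Control"]], ", Case = ", counts[["Case"]], call. = FALSE)
  add <- c(Control = 0L, Case = 0L)
  if (config$balance_first) {
    minority <- names(which.min(counts))
    add[minority] <- max(counts) - min(counts)
  }
  total <- sum(counts) + sum(add)
  if (total < config$target_total) {
    deficit <- config$target_total - total
    add[["Case"]] <- add[["Case"]] + ceiling(deficit / 2)
    add[["Control"]] <- add[["Control"]] + floor(deficit / 2)
  }
  if (sum(add) == 0L) return(table)
  pieces <- list(values = table$values,
                 labels = as.character(table$labels),
                 synthetic = table$synthetic)
  for (cls in c("Case", "Control")) {
    if (add[[cls]] == 0L) next
    base_rows <- table$values[real & table$labels == cls, , drop = FALSE]
    syn <- smote_points(base_rows, add[[cls]], k = config$k_neighbors,
                        seed = derive_seed(config$seed, "smote", cls))
    rownames(syn) <- sprintf("SMOTE_%s_%d", cls, seq_len(nrow(syn)))
    pieces$values <- rbind(pieces$values, syn)
    pieces$labels <- c(pieces$labels, rep(cls, nrow(syn)))
    pieces$synthetic <- c(pieces$synthetic, rep(TRUE, nrow(syn)))
  }
  feature_table(pieces$values, pieces$labels, synthetic = pieces$synthetic,
                informative = table$informative)
}
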
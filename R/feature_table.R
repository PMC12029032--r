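#' Construct a feature table
#'
#' The central container of the package: a samples x metabolites intensity
#' matrix with per-sample binary labels and a per-sample flag marking rows
#' created by SMOTE augmentation. Metabolomics tables are typically "wide and
#' short" (more metabolites than samples); nothing here assumes otherwise.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#'   Row names are sample IDs, column names are feature IDs; both must be
#'   unique and non-empty.
#' @param labels Character or factor of per-sample classes; must contain only
#'   `"Case"` and `"Control"`.
#' @param synthetic Logical vector flagging SMOTE-generated rows. Defaults to
#'   all-`FALSE` (all samples real).
#' @param informative Optional integer vector of ground-truth informative
#'   feature indices (attached by [simulate_feature_table()]).
#' @return An object of class `feature_table`.
#' @seealso [read_feature_table()], [write_feature_table()]
#' @export
feature_table <- function(values, labels, synthetic = NULL, informative = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("feature table contains missing or non-finite values", call. = FALSE)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must have sample IDs as row names and feature IDs as column names",
         call. = FALSE)
  if (nrow(values) == 0 && is.null(rownames(values)))
    rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop("`labels` must have one entry per sample", call. = FALSE)
  bad <- setdiff(unique(labels), c("Case", "Control"))
  if (length(bad))
    stop("labels must be 'Case' or 'Control'; found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(synthetic)) synthetic <- rep(FALSE, nrow(values))
  if (!is.logical(synthetic) || length(synthetic) != nrow(values) || anyNA(synthetic))
    stop("`synthetic` must be a logical vector with one entry per sample", call. = FALSE)
  structure(
    list(values = values,
         labels = factor(labels, levels = c("Control", "Case")),
         synthetic = synthetic,
         informative = informative),
    class = "feature_table")
}

#' @export
#' @method print feature_table
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  Case: %d  Control: %d  (synthetic: %d)\n",
              sum(x$labels == "Case"), sum(x$labels == "Control"),
              sum(x$synthetic)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

n_samples <- function(table) nrow(table$values)
n_features <- function(table) ncol(table$values)
sample_ids <- function(table) rownames(table$values)
feature_ids <- function(table) colnames(table$values)

#' Subset a feature table by samples and/or features
#'
#' @param x A `feature_table`.
#' @param i Sample index (integer, logical or sample IDs).
#' @param j Feature index (integer, logical or feature IDs).
#' @param ... Unused.
#' @return A `feature_table` restricted to the selected rows/columns.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  feature_table(x$values[i, j, drop = FALSE],
                as.character(x$labels)[i],
                synthetic = x$synthetic[i])
}

#' Read a feature table from CSV/TSV
#'
#' The first column is taken as the sample ID. The label column is mapped to
#' Case/Control through an explicit `label_map`: the sign convention of the
#' ensemble vote (+1 Case, -1 Control) depends on which class is "Case", so the
#' mapping is never guessed from alphabetical order. Missing values are
#' rejected, not imputed.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file; delimiter inferred
#'   from the extension.
#' @param label_column Name of the column (or, for `samples_in_columns`, row)
#'   holding the class labels.
#' @param label_map Named character vector mapping raw label values to
#'   `"Case"`/`"Control"`, e.g. `c(bacterial = "Case", control = "Control")`.
#'   May be omitted when the file already uses Case/Control.
#' @param orientation `"samples_in_rows"` (default) or `"samples_in_columns"`;
#'   the latter transposes the matrix after reading.
#' @param synthetic_column Optional name of a logical column marking
#'   SMOTE-generated rows (written by [write_feature_table()] when present).
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path, label_column = "label", label_map = NULL,
                               orientation = c("samples_in_rows", "samples_in_columns"),
                               synthetic_column = "synthetic") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("file has no feature columns: ", path, call. = FALSE)
  ids <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  if (orientation == "samples_in_columns") {
    # first column held feature IDs; remaining columns are samples
    feat_ids <- ids
    samp_ids <- colnames(body)
    body <- as.data.frame(t(as.matrix(body)), stringsAsFactors = FALSE)
    colnames(body) <- feat_ids
    ids <- samp_ids
  }
  if (!label_column %in% colnames(body))
    stop("label column '", label_column, "' not found in ", path, call. = FALSE)
  labels_raw <- body[[label_column]]
  body[[label_column]] <- NULL
  synthetic <- NULL
  if (!is.null(synthetic_column) && synthetic_column %in% colnames(body)) {
    synthetic <- toupper(body[[synthetic_column]]) %in% c("TRUE", "T", "1")
    body[[synthetic_column]] <- NULL
  }
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, colnames(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at sample '%s', feature '%s' in %s",
                 ids[bad[1]], colnames(body)[bad[2]], path), call. = FALSE)
  }
  rownames(vals) <- ids
  if (!is.null(label_map)) {
    unknown <- setdiff(unique(labels_raw), names(label_map))
    if (length(unknown))
      stop("label values not covered by `label_map`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    labels_raw <- unname(label_map[labels_raw])
  }
  lev <- unique(labels_raw)
  if (length(lev) != 2)
    stop("label column must have exactly two levels; found: ",
         paste(lev, collapse = ", "), call. = FALSE)
  feature_table(vals, labels_raw, synthetic = synthetic)
}

#' Write a feature table to CSV
#'
#' Sample IDs in the first column, feature IDs as header, the label column
#' appended, and a `synthetic` column when any row is flagged. Values are
#' printed at 17 significant digits so [read_feature_table()] inverts the
#' write bit-exactly.
#'
#' @param table A `feature_table`.
#' @param path Output path (`.csv`).
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) == 0L)
    stop("refusing to write an empty feature table (0 samples)", call. = FALSE)
  chr <- apply(table$values, c(1, 2), function(v) sprintf("%.17g", v))
  df <- data.frame(sample_id = rownames(table$values), chr,
                   label = as.character(table$labels),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (any(table$synthetic)) df$synthetic <- table$synthetic
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("failed to write '", path, "': ", conditionMessage(e),
                             call. = FALSE))
  invisible(path)
}

#' Write a structured result report as JSON
#'
#' Keys are emitted in a fixed order and floats at full precision, so two
#' writes of the same report are byte-identical. `NaN`/`NA` values (e.g. an
#' undefined rate on a zero denominator) serialize as JSON `null`.
#'
#' @param report A named list (typically the `report` element returned by
#'   [run_dweml()] or [fit_ensemble()]).
#' @param path Output path (`.json`).
#' @export
write_report <- function(report, path) {
  stopifnot(is.list(report))
  json <- tryCatch(
    jsonlite::toJSON(.sanitize_report(report), auto_unbox = TRUE, digits = NA,
                     null = "null", na = "null", pretty = TRUE),
    error = function(e) stop("report not serializable: ", conditionMessage(e),
                             call. = FALSE))
  writeLines(json, path)
  invisible(path)
}

# strip closures/models and map non-finite numbers to NA for JSON null
.sanitize_report <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) {
    out <- lapply(x, .sanitize_report)
    return(out[!vapply(out, is.null, logical(1))])
  }
  if (is.numeric(x)) x[!is.finite(x)] <- NA
  if (is.factor(x)) x <- as.character(x)
  x
}

#' Read a JSON report written by [write_report()]
#' @param path Path to the JSON file.
#' @return A named list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
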
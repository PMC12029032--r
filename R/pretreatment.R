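#' Total-area normalization
#'
#' Divides each sample's intensities by their sum, removing global intensity
#' differences between samples (dilution, injection volume). The default
#' pretreatment for untargeted metabolomics tables when the source study
#' specifies nothing else.
#'
#' @param table A [feature_table()] of non-negative intensities.
#' @return The table with every row summing to 1.
#' @export
normalize_total_area <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  rs <- rowSums(table$values)
  bad <- which(rs <= 0)
  if (length(bad))
    stop("total-area normalization requires positive row sums; offending sample(s): ",
         paste(rownames(table$values)[bad], collapse = ", "), call. = FALSE)
  table$values <- table$values / rs
  table
}

#' Log10 transformation
#'
#' Elementwise base-10 logarithm. Zeros are a domain error under the default
#' `error_on_nonpositive` policy; under `half_min_positive` an offset equal to
#' half the smallest strictly positive value in the whole table is added first
#' (a common metabolomics convention), so the data are never altered silently.
#'
#' @param table A [feature_table()] with non-negative values.
#' @param policy `"error_on_nonpositive"` (default) or `"half_min_positive"`.
#' @return The log10-transformed table.
#' @export
log10_transform <- function(table,
                            policy = c("error_on_nonpositive", "half_min_positive")) {
  stopifnot(inherits(table, "feature_table"))
  policy <- match.arg(policy)
  v <- table$values
  if (any(v < 0))
    stop("log10 transform requires non-negative values", call. = FALSE)
  if (policy == "error_on_nonpositive") {
    if (any(v == 0))
      stop("zero intensities present; use policy = 'half_min_positive' ",
           "to add a half-minimum offset", call. = FALSE)
    offset <- 0
  } else {
    pos <- v[v > 0]
    if (!length(pos)) stop("table has no positive values", call. = FALSE)
    offset <- min(pos) / 2
  }
  table$values <- log10(v + offset)
  table
}

# shared mean/SD scaling core; power = 1 (autoscale) or 0.5 (Pareto)
.scale_columns <- function(table, power, what) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) < 2)
    stop(what, " requires at least 2 samples", call. = FALSE)
  mu <- colMeans(table$values)
  sdv <- apply(table$values, 2, stats::sd)   # sample (n-1) SD
  const <- sdv == 0
  if (any(const)) {
    warning(sum(const), " constant feature column(s) set to zero: ",
            paste(utils::head(colnames(table$values)[const], 5), collapse = ", "),
            call. = FALSE)
    sdv[const] <- 1   # centered values are already 0
  }
  table$values <- sweep(sweep(table$values, 2, mu, "-"), 2, sdv^power, "/")
  table
}

#' Autoscaling (unit-variance scaling)
#'
#' Per feature: subtract the column mean and divide by the sample (n-1)
#' standard deviation. Constant columns become all-zero with a warning.
#'
#' @param table A [feature_table()] with at least two samples.
#' @return The autoscaled table (non-constant columns: mean 0, SD 1).
#' @export
autoscale <- function(table) .scale_columns(table, 1, "autoscale")

#' Pareto scaling
#'
#' Per feature: subtract the column mean and divide by the square root of the
#' sample standard deviation. A milder variance stabilizer than autoscaling
#' that keeps part of the original intensity structure; standard in
#' metabolomics. The scaled column SD equals the square root of the original.
#'
#' @param table A [feature_table()] with at least two samples.
#' @return The Pareto-scaled table.
#' @export
pareto_scale <- function(table) .scale_columns(table, 0.5, "Pareto scaling")

#' Apply an ordered pretreatment recipe
#'
#' Steps are applied strictly in the listed order; an empty recipe is the
#' identity. Recipes mirror the per-study conventions of metabolomics
#' pipelines, e.g. `c("total_area", "log10", "pareto")` or `"autoscale"`.
#'
#' @param table A [feature_table()].
#' @param recipe Character vector of step names, each one of
#'   `"total_area"`, `"log10"`, `"autoscale"`, `"pareto"`.
#' @param log_offset_policy Zero-handling policy passed to [log10_transform()].
#' @return The pretreated table.
#' @export
apply_recipe <- function(table, recipe = character(),
                         log_offset_policy = "error_on_nonpositive") {
  stopifnot(inherits(table, "feature_table"))
  known <- c("total_area", "log10", "autoscale", "pareto")
  bad <- setdiff(recipe, known)
  if (length(bad))
    stop("unknown pretreatment step(s): ", paste(bad, collapse = ", "),
         "; valid steps: ", paste(known, collapse = ", "), call. = FALSE)
  for (i in seq_along(recipe)) {
    table <- tryCatch(
      switch(recipe[i],
             total_area = normalize_total_area(table),
             log10      = log10_transform(table, log_offset_policy),
             autoscale  = autoscale(table),
             pareto     = pareto_scale(table)),
      error = function(e) stop("recipe step ", i, " ('", recipe[i], "'): ",
                               conditionMessage(e), call. = FALSE))
  }
  table
}
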
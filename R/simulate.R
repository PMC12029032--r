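#' Specification of a synthetic two-class metabolomics table
#'
#' Describes a wide-short case-control intensity table with known ground
#' truth. Latent per-sample profiles are correlated Gaussians
#' (block-exchangeable correlation, emulating co-regulated metabolite
#' groups); Case samples are shifted on a subset of informative features by a
#' chosen number of within-class SD units on the latent log scale; the latent
#' values are then mapped to positive, right-skewed intensities as
#' `10^(base_log_mean + base_log_sd * z)`, which makes total-area
#' normalization and log10 pretreatment meaningful on the simulated data.
#'
#' @param n_case,n_control Per-class sample counts (default 30/30).
#' @param n_features Number of features (default 200, a wide-short table).
#' @param n_informative Number of class-shifted features (default 10).
#' @param effect_size_sd Case shift of informative features, in within-class
#'   SD units on the latent scale (default 2).
#' @param base_log_mean,base_log_sd Location and spread of log10 intensities
#'   (defaults 5 and 0.4: peak areas around 1e5 spanning roughly two
#'   decades).
#' @param block_correlation Within-block latent correlation in \[0, 1)
#'   (default 0.2).
#' @param block_size Features per correlated block (default 10).
#' @param seed Integer seed; the generated table is bit-identical per seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_case = 30, n_control = 30, n_features = 200,
                           n_informative = 10, effect_size_sd = 2,
                           base_log_mean = 5, base_log_sd = 0.4,
                           block_correlation = 0.2, block_size = 10,
                           seed = 1) {
  stopifnot(n_case >= 2, n_control >= 2, n_features >= 1,
            n_informative >= 0, n_informative <= n_features,
            effect_size_sd >= 0, base_log_sd > 0,
            block_correlation >= 0, block_correlation < 1, block_size >= 1)
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size_sd = effect_size_sd,
                 base_log_mean = base_log_mean, base_log_sd = base_log_sd,
                 block_correlation = block_correlation,
                 block_size = as.integer(block_size),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic feature table
#'
#' @param spec A [synthetic_spec()].
#' @return A [feature_table()] of positive intensities with Case/Control
#'   labels; the indices of the informative features are attached as the
#'   `informative` element.
#' @export
simulate_feature_table <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_case + spec$n_control
  p <- spec$n_features
  rho <- spec$block_correlation
  block <- ((seq_len(p) - 1L) %/% spec$block_size) + 1L
  # block-exchangeable correlation: z = sqrt(rho) g_block + sqrt(1-rho) eps
  g <- matrix(stats::rnorm(n * max(block)), n, max(block))
  z <- sqrt(rho) * g[, block, drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
  labels <- rep(c("Case", "Control"), c(spec$n_case, spec$n_control))
  informative <- seq_len(spec$n_informative)
  if (spec$n_informative > 0)
    z[labels == "Case", informative] <-
      z[labels == "Case", informative] + spec$effect_size_sd
  vals <- 10^(spec$base_log_mean + spec$base_log_sd * z)
  dimnames(vals) <- list(sprintf("S%03d", seq_len(n)),
                         sprintf("M%03d", seq_len(p)))
  feature_table(vals, labels, informative = informative)
}
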
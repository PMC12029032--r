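#' Derive a reproducible stage seed from a master seed
#'
#' All randomness in a run flows from one master seed; every stage (fold
#' assignment, each learner fit, each permutation, SMOTE, the GA) draws its
#' own seed as a deterministic hash of the master seed and a stage tag, so a
#' stage can be re-run in isolation and still reproduce. Seeds stay in
#' `[1, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param ... Stage tag components (strings/integers), e.g.
#'   `derive_seed(7, "fit", "RF", fold)`.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(tag)) h <- (h * 131 + b) %% 2147483647
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h) %% 2147483646 + 1)
}
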
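#' Derive a component seed from a master seed
#'
#' Every stochastic component (LHS warm-up, k-means restarts, bootstrap
#' resamples, hill-climb perturbations, generators) draws its own seed
#' from the run's master seed through this splitter, so a whole pipeline
#' run is reproducible from a single integer and components stay
#' decoupled (adding draws to one phase does not shift another).
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  m <- as.numeric(master) %% 2147483647
  x <- (m * 69069 + as.numeric(index) * 104729 + 12345) %% 2147483629
  as.integer(x + 1)
}

# Run code under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
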
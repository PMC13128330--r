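# Planted-view recovery instance: W is a corrupted observation of a
# planted tree's similarity matrix. The corruption adds sparse strong
# spurious pairs (which mislead greedy linkage) plus light jitter; the
# planted view itself stays clean. Distractor views are label-permuted
# copies of the planted similarity: identical value distribution, no
# information about the planted structure.
recovery_instance <- function(seed, n = 24, p_out = 0.15, jitter = 0.05) {
  planted <- random_mergetree(n, seed = 1000 + seed)
  S1 <- tree_to_similarity(planted)
  W <- withr::with_seed(2000 + seed, {
    E <- matrix(0, n, n)
    out <- matrix(stats::runif(n * n) < p_out, n, n) & upper.tri(E)
    E[out] <- stats::runif(sum(out), 0.5, 1)
    E <- E + t(E)
    J <- matrix(stats::rnorm(n * n, sd = jitter), n, n)
    pmin(pmax(S1 + E + (J + t(J)) / 2, 0), 1.5)
  })
  diag(W) <- 0
  shuffled <- function(S, sd) {
    p <- withr::with_seed(sd, sample(nrow(S)))
    out <- S[p, p]
    dimnames(out) <- dimnames(S)
    out
  }
  list(
    W = as_similarity(W, rownames(S1)),
    planted = planted,
    views = list(planted = S1,
                 control1 = shuffled(S1, 3000 + seed),
                 control2 = shuffled(S1, 4000 + seed))
  )
}
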
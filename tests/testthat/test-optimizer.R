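make_problem <- function(n = 12, seed = 1) {
  W <- random_similarity(n, seed)
  views <- build_view_set(W, seed = seed)
  list(W = W, views = views)
}

test_that("optimal-variant fitness of identity equals the baseline cost", {
  pb <- make_problem(10, 3)
  spec <- fitness_spec("optimal", seed = 3)
  expect_equal(fitness(identity_params(3), pb$W, pb$views, spec),
               dasgupta_cost(pb$W, average_linkage(pb$W)))
})

test_that("robust fitness of identity is exactly 1 by normalization", {
  pb <- make_problem(14, 4)
  spec <- fitness_spec("robust", B_full = 5, B_cheap = 2, seed = 4)
  expect_equal(fitness(identity_params(3), pb$W, pb$views, spec), 1)
  # cheap evaluation uses a prefix of the same resamples
  expect_equal(fitness(identity_params(3), pb$W, pb$views, spec, B = 2), 1)
})

test_that("optimal variant forces single evaluations", {
  spec <- fitness_spec("optimal", B_full = 10, B_cheap = 3, seed = 1)
  expect_equal(spec$B_full, 1L)
  expect_equal(spec$B_cheap, 1L)
  expect_error(fitness_spec("robust", B_full = 2, B_cheap = 5), "B_cheap")
})

test_that("LHS warm-up seeds identity, stratifies, and is reproducible", {
  pb <- make_problem(10, 5)
  budget <- search_budget(n_warmup = 8, n_rounds = 1, n_inject = 1,
                          n_hill = 1, pool_size = 32)
  spec <- fitness_spec("optimal", seed = 5)
  tr <- lhs_warmup(pb$W, pb$views, budget, spec)
  expect_length(tr$fitness, 9)  # 8 LHS + identity as sample 0
  expect_equal(tr$params[1, ], params_to_vector_q(identity_params(3)))
  # per-dimension stratification of the raw (pre-projection) samples
  raw <- tr$raw[-1, , drop = FALSE]
  upper <- c(rep(1, 4), rep(4, 4))
  for (d in seq_len(ncol(raw))) {
    bins <- floor(raw[, d] / upper[d] * 8)
    expect_setequal(bins, 0:7)
  }
  tr2 <- lhs_warmup(pb$W, pb$views, budget, spec)
  expect_identical(tr, tr2)
})

test_that("the surrogate localizes the optimum of a known surface", {
  k <- 1
  withr::with_seed(99, {
    raw <- cbind(matrix(stats::runif(200 * 2), 200, 2),
                 matrix(stats::runif(200 * 2, 0, 4), 200, 2))
  })
  proj <- t(apply(raw, 1, function(v) params_to_vector_q(
    project_params(v, k))))
  truef <- function(M) (M[, 3] - 2)^2 + (M[, 4] - 1)^2  # quadratic in pw, ps
  tr <- dendroblend:::new_trace(4)
  for (i in seq_len(nrow(raw))) {
    tr <- dendroblend:::trace_add(tr, raw[i, ], proj[i, ], truef(proj)[i],
                                  "warmup", "full")
  }
  model <- fit_surrogate(tr, seed = 7)
  prop <- propose(model, k, pool_size = 512, n_inject = 1, seed = 7)
  expect_false(prop$fallback)
  ref <- withr::with_seed(123, {
    m <- cbind(matrix(stats::runif(2000 * 2), 2000, 2),
               matrix(stats::runif(2000 * 2, 0, 4), 2000, 2))
    truef(t(apply(m, 1, function(v) params_to_vector_q(
      project_params(v, k)))))
  })
  expect_lte(truef(prop$params), stats::quantile(ref, 0.1))
})

test_that("a constant trace triggers the random-injection fallback", {
  tr <- dendroblend:::new_trace(4)
  withr::with_seed(1, {
    for (i in 1:12) {
      raw <- c(stats::runif(2), stats::runif(2, 0, 4))
      v <- params_to_vector_q(project_params(raw, 1))
      tr <- dendroblend:::trace_add(tr, raw, v, 5, "warmup", "full")
    }
  })
  model <- fit_surrogate(tr, seed = 1)
  expect_true(model$constant)
  prop <- propose(model, 1, pool_size = 64, n_inject = 2, seed = 2)
  expect_true(prop$fallback)
  expect_equal(nrow(prop$params), 2)
})

test_that("hill climbing is accept-only-improving", {
  pb <- make_problem(10, 6)
  spec <- fitness_spec("optimal", seed = 6)
  start <- params_to_vector_q(identity_params(3))
  hc0 <- hill_climb(start, pb$W, pb$views, spec, steps = 0, seed = 1)
  expect_identical(hc0$vec, start)

  hc <- hill_climb(start, pb$W, pb$views, spec, steps = 15, seed = 1)
  start_fit <- fitness(identity_params(3), pb$W, pb$views, spec,
                       B = spec$B_cheap)
  expect_lte(hc$cheap, start_fit)
  # replay acceptance: the accepted-fitness sequence strictly decreases
  cur <- start_fit
  accepted <- numeric(0)
  for (f in hc$fitness) {
    if (f < cur) {
      accepted <- c(accepted, f)
      cur <- f
    }
  }
  expect_true(length(accepted) <= 1 || all(diff(accepted) < 0))
  expect_equal(hc$cheap, cur)
})

test_that("optimize is reproducible and never above the baseline", {
  pb <- make_problem(12, 7)
  budget <- search_budget(n_warmup = 8, n_rounds = 2, n_inject = 2,
                          n_hill = 4, pool_size = 64)
  spec <- fitness_spec("optimal", seed = 7)
  r1 <- optimize_blend(pb$W, pb$views, budget, spec)
  r2 <- optimize_blend(pb$W, pb$views, budget, spec)
  expect_identical(r1$trace$fitness, r2$trace$fitness)
  expect_identical(r1$params, r2$params)
  expect_identical(r1$tree$merge, r2$tree$merge)
  expect_lte(r1$cost, r1$baseline_cost + 1e-12)
  curve <- best_so_far(r1$trace)
  expect_true(all(diff(curve) <= 0))
})

test_that("a larger round budget can only improve the best-so-far", {
  pb <- make_problem(10, 8)
  spec <- fitness_spec("optimal", seed = 8)
  small <- optimize_blend(pb$W, pb$views,
                          search_budget(8, 2, 2, 4, 64), spec)
  large <- optimize_blend(pb$W, pb$views,
                          search_budget(8, 4, 2, 4, 64), spec)
  expect_lte(large$fitness, small$fitness + 1e-12)
})
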
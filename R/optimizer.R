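#' Fitness specification
#'
#' Two fitness variants drive the search over blending parameters. The
#' `optimal` variant scores a candidate by the Dasgupta cost of average
#' linkage applied to its blended matrix, measured on the full input.
#' The `robust` variant scores it by the mean, over `B` bootstrap
#' subsamples of the items, of that cost normalized by the plain
#' average-linkage cost on the same subsample; rewarding parameters
#' whose solutions survive data perturbation mitigates overfitting.
#' Two evaluation levels keep the budget manageable: expensive "full"
#' evaluations use `B_full` resamples, cheap hill-climb evaluations use
#' `B_cheap`.
#'
#' @param variant `"robust"` or `"optimal"`.
#' @param B_full bootstrap count for full evaluations.
#' @param B_cheap bootstrap count for cheap evaluations
#'   (`B_cheap <= B_full`).
#' @param seed integer master seed for resampling.
#' @return an object of class `fitness_spec`.
#' @export
fitness_spec <- function(variant = c("robust", "optimal"), B_full = 10,
                         B_cheap = 3, seed = 1) {
  variant <- match.arg(variant)
  if (variant == "optimal") {
    B_full <- 1L
    B_cheap <- 1L
  }
  B_full <- as.integer(B_full)
  B_cheap <- as.integer(B_cheap)
  if (B_full < 1L || B_cheap < 1L || B_cheap > B_full) {
    stop("need 1 <= B_cheap <= B_full")
  }
  structure(list(variant = variant, B_full = B_full, B_cheap = B_cheap,
                 seed = as.integer(seed)),
            class = "fitness_spec")
}

#' Search budget
#'
#' Sizes of the three optimizer phases: Latin-hypercube warm-up,
#' surrogate-guided candidate injection, and local hill-climbing.
#' Defaults are sized for inputs up to a few hundred items.
#'
#' @param n_warmup LHS warm-up samples.
#' @param n_rounds iterative rounds after the warm-up.
#' @param n_inject surrogate-proposed candidates per round.
#' @param n_hill hill-climb steps per round.
#' @param pool_size surrogate screening pool per round.
#' @return an object of class `search_budget`.
#' @export
search_budget <- function(n_warmup = 64, n_rounds = 10, n_inject = 4,
                          n_hill = 20, pool_size = 2048) {
  b <- lapply(list(n_warmup = n_warmup, n_rounds = n_rounds,
                   n_inject = n_inject, n_hill = n_hill,
                   pool_size = pool_size), as.integer)
  if (any(unlist(b) < 1L)) stop("all budget fields must be positive")
  structure(b, class = "search_budget")
}

# Bootstrap subsample index sets: n draws with replacement, collapsed
# to the unique items, so the resampled similarity stays a valid
# submatrix (duplicated rows would create artificial zero-distance
# twins in the linkage).
resample_sets <- function(n, B, seed) {
  lapply(seq_len(B), function(b) {
    idx <- integer(0)
    tries <- 0L
    while (length(idx) < 2L) {
      idx <- with_seed(derive_seed(seed, 7000L + b + 100000L * tries),
                       sort(unique(sample.int(n, n, replace = TRUE))))
      tries <- tries + 1L
    }
    idx
  })
}

# Precomputed per-spec context: resample index sets, the corresponding
# submatrices of W and the views, and the plain average-linkage
# baseline cost of each resample.
fitness_cache <- function(W, views, spec) {
  if (spec$variant == "optimal") return(NULL)
  n <- nrow(W)
  res <- resample_sets(n, spec$B_full, spec$seed)
  list(
    resamples = res,
    W = lapply(res, function(idx) W[idx, idx, drop = FALSE]),
    views = lapply(res, function(idx) {
      lapply(views, function(V) V[idx, idx, drop = FALSE])
    }),
    baseline = vapply(res, function(idx) {
      Wb <- W[idx, idx, drop = FALSE]
      dasgupta_cost(Wb, average_linkage(Wb))
    }, numeric(1))
  )
}

#' Fitness of a blending parameter set
#'
#' See [fitness_spec()] for the two variants. The robust fitness of the
#' identity configuration is exactly 1 by construction of the
#' normalization, giving an absolute reference point.
#'
#' @param params a [blend_params()].
#' @param W similarity matrix.
#' @param views view set (see [build_view_set()]).
#' @param spec a [fitness_spec()].
#' @param B number of resamples to use (defaults to `spec$B_full`;
#'   ignored by the optimal variant).
#' @param cache internal precomputed context; recomputed when `NULL`.
#' @return scalar fitness (lower is better).
#' @export
fitness <- function(params, W, views, spec, B = NULL, cache = NULL) {
  if (spec$variant == "optimal") {
    return(dasgupta_cost(W, average_linkage(blend(W, views, params))))
  }
  if (is.null(B)) B <- spec$B_full
  if (is.null(cache)) cache <- fitness_cache(W, views, spec)
  ratios <- vapply(seq_len(B), function(b) {
    Wb <- cache$W[[b]]
    cb <- dasgupta_cost(Wb, average_linkage(blend(Wb, cache$views[[b]],
                                                  params)))
    base <- cache$baseline[b]
    if (base <= 0) 1 else cb / base
  }, numeric(1))
  mean(ratios)
}

new_trace <- function(d) {
  structure(list(raw = matrix(numeric(0), 0, d),
                 params = matrix(numeric(0), 0, d),
                 fitness = numeric(0), phase = character(0),
                 kind = character(0)),
            class = "search_trace")
}

trace_add <- function(trace, raw, params, fitness, phase, kind) {
  trace$raw <- rbind(trace$raw, raw)
  trace$params <- rbind(trace$params, params)
  trace$fitness <- c(trace$fitness, fitness)
  trace$phase <- c(trace$phase, phase)
  trace$kind <- c(trace$kind, kind)
  trace
}

#' Best-so-far curve of a search trace
#'
#' Running minimum of the fully evaluated fitness values, in evaluation
#' order; non-increasing by construction.
#'
#' @param trace a `search_trace` from [optimize_blend()].
#' @return numeric vector.
#' @export
best_so_far <- function(trace) {
  cummin(trace$fitness[trace$kind == "full"])
}

#' Latin-hypercube warm-up
#'
#' Draws `n_warmup` LHS samples over the raw parameter box
#' (coefficients in `[0, 1]` before projection, exponents in `[0, 4]`),
#' projects each onto the feasible set and evaluates it with the full
#' fitness. The identity configuration is always included as sample 0,
#' so the plain average-linkage baseline is in every candidate set.
#'
#' @inheritParams fitness
#' @param budget a [search_budget()].
#' @return a `search_trace`.
#' @export
lhs_warmup <- function(W, views, budget, spec, cache = NULL) {
  k <- length(views)
  d <- 2L * k + 2L
  if (budget$n_warmup < 2L) stop("n_warmup must be at least 2")
  if (is.null(cache)) cache <- fitness_cache(W, views, spec)
  U <- with_seed(derive_seed(spec$seed, 1L),
                 lhs::randomLHS(budget$n_warmup, d))
  U[, seq.int(k + 2L, d)] <- U[, seq.int(k + 2L, d)] * 4
  trace <- new_trace(d)
  idv <- params_to_vector(identity_params(k))
  trace <- trace_add(trace, idv, idv,
                     fitness(identity_params(k), W, views, spec,
                             cache = cache),
                     "warmup", "full")
  for (s in seq_len(nrow(U))) {
    p <- project_params(U[s, ], k)
    trace <- trace_add(trace, U[s, ], params_to_vector(p),
                       fitness(p, W, views, spec, cache = cache),
                       "warmup", "full")
  }
  trace
}

#' Fit the surrogate fitness model
#'
#' A random-forest regressor mapping projected parameter vectors to
#' their fully evaluated fitness. A tree ensemble handles the
#' non-smooth, interaction-heavy response of the blending model with no
#' kernel tuning. It is trained once on the warm-up and reused
#' unchanged in every later round. A degenerate trace (all fitness
#' values identical) yields a constant model, and proposals fall back
#' to uniform random injection.
#'
#' @param trace a `search_trace`.
#' @param seed integer seed for the forest.
#' @return an object of class `surrogate_model`.
#' @export
fit_surrogate <- function(trace, seed = 1) {
  full <- trace$kind == "full"
  x <- trace$params[full, , drop = FALSE]
  y <- trace$fitness[full]
  if (nrow(x) < 2L) stop("surrogate needs at least 2 full evaluations")
  if (stats::sd(y) < 1e-12) {
    return(structure(list(constant = TRUE, value = y[1]),
                     class = "surrogate_model"))
  }
  rf <- with_seed(derive_seed(seed, 2L), suppressWarnings(
    randomForest::randomForest(x = x, y = y, ntree = 300)))
  structure(list(constant = FALSE, model = rf), class = "surrogate_model")
}

#' Propose candidates with the surrogate
#'
#' Draws `pool_size` uniform random raw vectors, projects them,
#' predicts their fitness with the surrogate and returns the `n_inject`
#' lowest-predicted candidates for true full evaluation. With a
#' constant surrogate the proposals are uniform random (fallback).
#'
#' @param model a `surrogate_model`.
#' @param k number of views.
#' @param pool_size screening pool size.
#' @param n_inject number of candidates to return.
#' @param seed integer seed.
#' @return list with matrices `raw` and `params` (one candidate per
#'   row) and logical `fallback`.
#' @export
propose <- function(model, k, pool_size, n_inject, seed = 1) {
  d <- 2L * k + 2L
  raw <- with_seed(derive_seed(seed, 3L), {
    m <- matrix(stats::runif(pool_size * d), pool_size, d)
    m[, seq.int(k + 2L, d)] <- m[, seq.int(k + 2L, d)] * 4
    m
  })
  proj <- t(apply(raw, 1, function(v) params_to_vector(project_params(v, k))))
  if (model$constant) {
    take <- with_seed(derive_seed(seed, 4L),
                      sample.int(nrow(raw), n_inject))
    return(list(raw = raw[take, , drop = FALSE],
                params = proj[take, , drop = FALSE], fallback = TRUE))
  }
  pred <- stats::predict(model$model, proj)
  take <- order(pred)[seq_len(n_inject)]
  list(raw = raw[take, , drop = FALSE],
       params = proj[take, , drop = FALSE], fallback = FALSE)
}

#' Local hill climbing
#'
#' Gaussian perturbation of the incumbent's raw vector (sd 0.1 on
#' coefficients, 0.25 on exponents), projected and scored with the
#' cheap fitness; a step is accepted only if strictly better, so the
#' accepted-fitness sequence is strictly decreasing. The result is
#' re-scored with the full fitness by the caller.
#'
#' @inheritParams fitness
#' @param start projected parameter vector to start from.
#' @param steps number of perturbation steps (0 returns the start).
#' @param seed integer seed.
#' @return list with `vec` (best projected vector found), `cheap` (its
#'   cheap fitness), and matrices/vectors of all evaluated candidates
#'   (`raw`, `params`, `fitness`).
#' @export
hill_climb <- function(start, W, views, spec, steps, seed = 1,
                       cache = NULL) {
  k <- length(views)
  d <- 2L * k + 2L
  if (is.null(cache)) cache <- fitness_cache(W, views, spec)
  cur <- start
  cur_fit <- fitness(vector_to_params(cur, k), W, views, spec,
                     B = spec$B_cheap, cache = cache)
  raw <- matrix(numeric(0), 0, d)
  par <- matrix(numeric(0), 0, d)
  fit <- numeric(0)
  sds <- c(rep(0.1, k + 1L), rep(0.25, k + 1L))
  for (t in seq_len(steps)) {
    cand_raw <- cur + with_seed(derive_seed(seed, 100L + t),
                                stats::rnorm(d, sd = sds))
    p <- project_params(cand_raw, k)
    v <- params_to_vector(p)
    f <- fitness(p, W, views, spec, B = spec$B_cheap, cache = cache)
    raw <- rbind(raw, cand_raw)
    par <- rbind(par, v)
    fit <- c(fit, f)
    if (f < cur_fit) {
      cur <- v
      cur_fit <- f
    }
  }
  list(vec = cur, cheap = cur_fit, raw = raw, params = par, fitness = fit)
}

#' Surrogate-assisted search over blending parameters
#'
#' Three phases balancing exploration and exploitation: (1) LHS warm-up
#' with the identity configuration seeded in, (2) one-time training of
#' the surrogate, (3) iterative rounds that inject the surrogate's most
#' promising candidates (fully evaluated) and refine the incumbent by
#' cheap-fitness hill climbing, re-scoring the refined point with the
#' full fitness. The returned fitness is never worse than the identity
#' configuration's, and the whole run is reproducible from
#' `spec$seed`.
#'
#' @inheritParams fitness
#' @param budget a [search_budget()].
#' @return list with `params` (best [blend_params()]), `tree` (average
#'   linkage on the best blended matrix), `cost` (its Dasgupta cost on
#'   `W`), `fitness` (best full fitness), `baseline_cost` (plain
#'   average-linkage cost on `W`), `baseline_fitness` (identity
#'   configuration's full fitness) and `trace`.
#' @export
optimize_blend <- function(W, views, budget = search_budget(),
                           spec = fitness_spec()) {
  W <- as_similarity(W)
  views <- lapply(views, function(V) {
    align_similarity(as_similarity(V), rownames(W))
  })
  k <- length(views)
  cache <- fitness_cache(W, views, spec)
  trace <- lhs_warmup(W, views, budget, spec, cache = cache)
  model <- fit_surrogate(trace, seed = spec$seed)  # trained once
  for (r in seq_len(budget$n_rounds)) {
    prop <- propose(model, k, budget$pool_size, budget$n_inject,
                    seed = derive_seed(spec$seed, 300L + r))
    for (s in seq_len(nrow(prop$params))) {
      p <- vector_to_params(prop$params[s, ], k)
      trace <- trace_add(trace, prop$raw[s, ], prop$params[s, ],
                         fitness(p, W, views, spec, cache = cache),
                         "injected", "full")
    }
    full <- which(trace$kind == "full")
    inc <- full[which.min(trace$fitness[full])]
    hc <- hill_climb(trace$params[inc, ], W, views, spec,
                     steps = budget$n_hill,
                     seed = derive_seed(spec$seed, 400L + r),
                     cache = cache)
    if (length(hc$fitness)) {
      for (s in seq_along(hc$fitness)) {
        trace <- trace_add(trace, hc$raw[s, ], hc$params[s, ],
                           hc$fitness[s], "hillclimb", "cheap")
      }
    }
    p <- vector_to_params(hc$vec, k)
    trace <- trace_add(trace, hc$vec, hc$vec,
                       fitness(p, W, views, spec, cache = cache),
                       "hillclimb", "full")
  }
  full <- which(trace$kind == "full")
  best <- full[which.min(trace$fitness[full])]
  best_params <- vector_to_params(trace$params[best, ], k)
  tree <- average_linkage(blend(W, views, best_params))
  baseline_tree <- average_linkage(W)
  list(
    params = best_params,
    tree = tree,
    cost = dasgupta_cost(W, tree),
    fitness = trace$fitness[best],
    baseline_cost = dasgupta_cost(W, baseline_tree),
    baseline_fitness = trace$fitness[full][1],
    trace = trace
  )
}
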
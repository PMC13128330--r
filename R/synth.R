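#' Synthetic benchmark generators
#'
#' Five generator families covering the benchmark's data topologies:
#' \describe{
#'   \item{`irregular`}{Gaussian clusters with random anisotropic
#'     covariances and unequal sizes.}
#'   \item{`spherical`}{well-separated isotropic Gaussians (centers at
#'     least 6 standard deviations apart, so recovery is forced).}
#'   \item{`nonconvex`}{interleaved half-moon point sets.}
#'   \item{`nested`}{a two-level hierarchy of Gaussians (super-centers
#'     containing sub-centers) with the hierarchy paths populated.}
#'   \item{`discrete`}{random binary features with block-planted bits,
#'     guaranteeing tied Hamming similarities (each block starts with
#'     two exact prototype copies).}
#' }
#' Free parameters not fixed by the caller (cluster counts,
#' dimensions, noise) are drawn from documented ranges under `seed`:
#' cluster counts 3-8, dimensions 2-16, flip noise 0.05.
#'
#' @param type one of `"irregular"`, `"spherical"`, `"nonconvex"`,
#'   `"nested"`, `"discrete"`.
#' @param n number of items (>= 4).
#' @param seed integer seed; the generator is deterministic given it.
#' @param k optional number of clusters (where meaningful).
#' @param d optional feature dimension.
#' @return list with `X` (feature matrix, rownames are item ids),
#'   `labels` (named character class per item), `hierarchy` (named
#'   character of `coarse/fine` paths, `nested` type only, else
#'   `NULL`), `type`, `seed`, `params`.
#' @export
generate_dataset <- function(type, n, seed = 1, k = NULL, d = NULL) {
  types <- c("irregular", "spherical", "nonconvex", "nested", "discrete")
  if (!type %in% types) {
    stop("unknown generator type '", type, "'; use one of ",
         paste(types, collapse = ", "))
  }
  if (n < 4) stop("n must be at least 4")
  out <- with_seed(derive_seed(seed, 11L), switch(
    type,
    irregular = gen_irregular(n, k, d),
    spherical = gen_spherical(n, k, d),
    nonconvex = gen_nonconvex(n),
    nested = gen_nested(n),
    discrete = gen_discrete(n, k, d)
  ))
  ids <- sprintf("item%03d", seq_len(n))
  rownames(out$X) <- ids
  names(out$labels) <- ids
  if (!is.null(out$hierarchy)) names(out$hierarchy) <- ids
  out$type <- type
  out$seed <- seed
  out
}

# split n items over k clusters, each cluster >= min_size
cluster_sizes <- function(n, k, min_size = 2L) {
  w <- stats::rgamma(k, shape = 2)
  sz <- pmax(min_size, floor(n * w / sum(w)))
  while (sum(sz) > n) sz[which.max(sz)] <- sz[which.max(sz)] - 1L
  while (sum(sz) < n) sz[which.min(sz)] <- sz[which.min(sz)] + 1L
  sz
}

gen_irregular <- function(n, k, d) {
  if (is.null(k)) k <- sample(3:8, 1)
  if (is.null(d)) d <- sample(2:16, 1)
  sz <- cluster_sizes(n, k)
  X <- NULL
  lab <- character(0)
  for (j in seq_len(k)) {
    mu <- stats::rnorm(d, sd = 8)
    A <- matrix(stats::rnorm(d * d, sd = 1), d, d)
    pts <- matrix(stats::rnorm(sz[j] * d), sz[j], d) %*% A +
      matrix(mu, sz[j], d, byrow = TRUE)
    X <- rbind(X, pts)
    lab <- c(lab, rep(paste0("C", j), sz[j]))
  }
  list(X = X, labels = lab, hierarchy = NULL,
       params = list(k = k, d = d, sizes = sz))
}

gen_spherical <- function(n, k, d) {
  if (is.null(k)) k <- 4L
  if (is.null(d)) d <- 2L
  # centers on a random subset of a grid with spacing 10 sigma (sigma=1),
  # guaranteeing >= 6 sigma separation
  side <- ceiling(k^(1 / d)) + 1L
  grid <- as.matrix(expand.grid(rep(list(seq_len(side) * 10), d)))
  ctr <- grid[sample.int(nrow(grid), k), , drop = FALSE]
  sz <- cluster_sizes(n, k)
  X <- NULL
  lab <- character(0)
  for (j in seq_len(k)) {
    pts <- matrix(stats::rnorm(sz[j] * d), sz[j], d) +
      matrix(ctr[j, ], sz[j], d, byrow = TRUE)
    X <- rbind(X, pts)
    lab <- c(lab, rep(paste0("C", j), sz[j]))
  }
  list(X = X, labels = lab, hierarchy = NULL,
       params = list(k = k, d = d, sizes = sz, spacing = 10))
}

gen_nonconvex <- function(n, noise = 0.08) {
  n1 <- ceiling(n / 2)
  n2 <- n - n1
  t1 <- stats::runif(n1, 0, pi)
  t2 <- stats::runif(n2, 0, pi)
  X <- rbind(
    cbind(cos(t1), sin(t1)),
    cbind(1 - cos(t2), 0.5 - sin(t2))
  ) + matrix(stats::rnorm(n * 2, sd = noise), n, 2)
  list(X = X, labels = rep(c("moon1", "moon2"), c(n1, n2)),
       hierarchy = NULL, params = list(noise = noise))
}

gen_nested <- function(n) {
  n_super <- sample(2:3, 1)
  n_sub <- sample(2:3, 1)
  d <- 2L
  leaves <- n_super * n_sub
  sz <- cluster_sizes(n, leaves)
  X <- NULL
  lab <- character(0)
  hier <- character(0)
  idx <- 0L
  super_ctr <- matrix(stats::rnorm(n_super * d, sd = 40), n_super, d)
  for (s in seq_len(n_super)) {
    for (u in seq_len(n_sub)) {
      idx <- idx + 1L
      mu <- super_ctr[s, ] + stats::rnorm(d, sd = 6)
      pts <- matrix(stats::rnorm(sz[idx] * d), sz[idx], d) +
        matrix(mu, sz[idx], d, byrow = TRUE)
      X <- rbind(X, pts)
      fine <- paste0("S", s, ".", u)
      lab <- c(lab, rep(fine, sz[idx]))
      hier <- c(hier, rep(paste0("S", s, "/", fine), sz[idx]))
    }
  }
  list(X = X, labels = lab, hierarchy = hier,
       params = list(n_super = n_super, n_sub = n_sub, d = d, sizes = sz))
}

gen_discrete <- function(n, k, d, flip = 0.05) {
  if (is.null(k)) k <- sample(3:5, 1)
  if (is.null(d)) d <- 32L
  sz <- cluster_sizes(n, k, min_size = 3L)
  X <- NULL
  lab <- character(0)
  for (j in seq_len(k)) {
    proto <- stats::rbinom(d, 1, 0.5)
    pts <- matrix(proto, sz[j], d, byrow = TRUE)
    # rows beyond the first two get independent bit flips; the two
    # exact prototype copies per block plant guaranteed similarity ties
    if (sz[j] > 2L) {
      fl <- matrix(stats::rbinom((sz[j] - 2L) * d, 1, flip),
                   sz[j] - 2L, d)
      pts[-(1:2), ] <- (pts[-(1:2), , drop = FALSE] + fl) %% 2
    }
    X <- rbind(X, pts)
    lab <- c(lab, rep(paste0("C", j), sz[j]))
  }
  list(X = X, labels = lab, hierarchy = NULL,
       params = list(k = k, d = d, sizes = sz, flip = flip))
}

#' Adversarial decoy-clique instance
#'
#' Constructs the weighted-clique instance that deceives average
#' linkage. Items form a `kappa^2 x kappa` grid: each grid row is a
#' small decoy clique of `kappa` items with internal similarity
#' `s + eps`, each grid column is a large optimal clique of `kappa^2`
#' items with internal similarity `s`; all other pairs are 0. Because
#' the average similarity is maximized inside the decoy cliques, an
#' average-linkage algorithm merges them first and never recovers the
#' globally coherent columns. Also returns the column-first reference
#' tree (each optimal clique merged into a balanced subtree, the
#' subtrees then joined balanced), whose Dasgupta cost defines the
#' optimal possible improvement on this instance.
#'
#' @param kappa clique parameter (>= 2); the instance has `kappa^3`
#'   items.
#' @param s base similarity (> 0).
#' @param eps decoy bonus (> 0).
#' @return list with `W` (similarity matrix), `reference` (column-first
#'   [mergetree()]), `row` and `col` (named grid assignments).
#' @export
decoy_cliques <- function(kappa, s = 1, eps = 0.1) {
  if (kappa < 2) stop("kappa must be >= 2")
  if (s <= 0 || eps <= 0) stop("s and eps must be positive")
  n_row <- kappa^2
  n_col <- kappa
  n <- n_row * n_col
  row <- rep(seq_len(n_row), each = n_col)
  col <- rep(seq_len(n_col), times = n_row)
  ids <- sprintf("r%02dc%d", row, col)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  W[outer(row, row, "==")] <- s + eps
  W[outer(col, col, "==")] <- s
  diag(W) <- 0
  W <- as_similarity(W)
  nested <- balanced_nested(lapply(seq_len(n_col), function(cc) {
    balanced_nested(which(col == cc))
  }))
  reference <- tree_from_nested(nested, ids)
  names(row) <- ids
  names(col) <- ids
  list(W = W, reference = reference, row = row, col = col)
}

#' Synthetic term ontology with annotated items
#'
#' Stand-in for a cell-ontology-style evaluation setting: a rooted term
#' DAG (a tree plus a few extra parent edges, mimicking multi-parent
#' terms), items annotated to leaf terms, and a feature matrix whose
#' cluster means follow the hierarchy (sibling terms are closer in
#' feature space than distant ones). This object is synthetic and only
#' emulates the shape of a curated ontology.
#'
#' @param depth tree depth (>= 2; root is depth 0).
#' @param branching children per internal term.
#' @param n_items number of annotated items.
#' @param seed integer seed.
#' @param extra_parents number of extra (multi-parent) edges to add.
#' @param d feature dimension.
#' @return list with `ontology` (list: `parents` named list
#'   child -> parents, `terms`, `root`), `annotations` (named character
#'   item -> leaf term) and `X` (feature matrix).
#' @export
synthetic_ontology <- function(depth = 3, branching = 2, n_items = 60,
                               seed = 1, extra_parents = 1, d = 8) {
  if (depth < 2) stop("depth must be >= 2")
  with_seed(derive_seed(seed, 31L), {
    parents <- list()
    level <- list("T")
    means <- list(T = rep(0, d))
    for (l in seq_len(depth)) {
      nxt <- character(0)
      for (p in unlist(level)) {
        for (b in seq_len(branching)) {
          ch <- paste0(p, ".", b)
          parents[[ch]] <- p
          # displacement shrinks with depth so siblings stay closest
          means[[ch]] <- means[[p]] + stats::rnorm(d, sd = 12 / 2^(l - 1))
          nxt <- c(nxt, ch)
        }
      }
      level <- as.list(nxt)
    }
    terms <- c("T", names(parents))
    leaves <- unlist(level)
    non_leaves <- setdiff(terms, leaves)
    if (extra_parents > 0) {
      for (e in seq_len(extra_parents)) {
        ch <- sample(names(parents), 1)
        depth_of <- function(t) lengths(regmatches(t, gregexpr(".", t,
                                                               fixed = TRUE)))
        shallower <- non_leaves[depth_of(non_leaves) < depth_of(ch)]
        anc <- ontology_ancestors(list(parents = parents), ch)
        pool <- setdiff(shallower, c(anc, ch))
        if (length(pool)) {
          parents[[ch]] <- unique(c(parents[[ch]], sample(pool, 1)))
        }
      }
    }
    ann <- sample(leaves, n_items, replace = TRUE)
    ids <- sprintf("item%03d", seq_len(n_items))
    names(ann) <- ids
    X <- t(vapply(ann, function(t) means[[t]] + stats::rnorm(d),
                  numeric(d)))
    rownames(X) <- ids
    list(ontology = list(parents = parents, terms = terms, root = "T"),
         annotations = ann, X = X)
  })
}

#' Ancestor closure of a term
#'
#' All terms reachable from `term` by following parent edges
#' (excluding `term` itself).
#'
#' @param ontology ontology list with a `parents` named list.
#' @param term term identifier.
#' @return character vector of ancestor terms.
#' @export
ontology_ancestors <- function(ontology, term) {
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    ps <- unique(unlist(ontology$parents[frontier]))
    ps <- setdiff(ps, seen)
    seen <- c(seen, ps)
    frontier <- ps
  }
  seen
}
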
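# Structurally diverse dendrogram views of a similarity matrix.
#
# Each view algorithm returns a mergetree; build_view_set() converts the
# trees back into similarity matrices so they can be blended with the
# original input. When a geometric view (k-means, centroid) has no
# feature matrix to work with, the rows of W are used as coordinate
# vectors: simple, deterministic and parameter-free.

# Connected components of a non-negative weight matrix (edges = W > 0).
graph_components <- function(M) {
  n <- nrow(M)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(M[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Recursive spectral bisection view
#'
#' Divisive, global view: treats `W` as a weighted graph, computes the
#' Fiedler vector (eigenvector of the second-smallest eigenvalue of the
#' symmetric normalized Laplacian `I - D^{-1/2} W D^{-1/2}`), sorts the
#' items by their Fiedler value and splits at the largest consecutive
#' gap, recursing on both sides. Disconnected blocks are split
#' component-first; an all-zero block falls back to a balanced index
#' split.
#'
#' @param W similarity matrix.
#' @return a [mergetree()].
#' @export
laplacian_bisection_view <- function(W) {
  W <- as_similarity(W)
  split_fun <- function(idx) {
    m <- length(idx)
    if (m == 2L) return(list(idx[1], idx[2]))
    M <- W[idx, idx, drop = FALSE]
    if (max(M) == 0) {
      # no edges at all: arbitrary balanced split
      h <- ceiling(m / 2)
      return(list(idx[seq_len(h)], idx[-seq_len(h)]))
    }
    comp <- graph_components(M)
    if (max(comp) > 1L) {
      left <- comp == comp[1]  # component of the smallest index
      return(list(idx[left], idx[!left]))
    }
    d <- rowSums(M)
    Dv <- 1 / sqrt(d)
    L <- diag(m) - (Dv * M) * rep(Dv, each = m)
    ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
    f <- ev$vectors[, m - 1L]
    nz <- which(abs(f) > 1e-12)
    if (length(nz) && f[nz[1]] < 0) f <- -f
    ord <- order(f, seq_len(m))
    gaps <- diff(f[ord])
    cand <- which(gaps >= max(gaps) - 1e-12)
    bal <- abs(cand - m / 2)
    cand <- cand[bal == min(bal)]
    s <- cand[1]
    list(idx[ord[seq_len(s)]], idx[ord[-seq_len(s)]])
  }
  divisive_tree(nrow(W), rownames(W), split_fun)
}

# Generic divisive builder: split_fun(idx) -> list(left_idx, right_idx).
divisive_tree <- function(n, labels, split_fun) {
  nest <- function(idx) {
    if (length(idx) == 1L) return(idx[1])
    p <- split_fun(sort(idx))
    if (length(p[[1]]) == 0L || length(p[[2]]) == 0L) {
      idx <- sort(idx)
      h <- ceiling(length(idx) / 2)
      p <- list(idx[seq_len(h)], idx[-seq_len(h)])
    }
    list(nest(p[[1]]), nest(p[[2]]))
  }
  tree_from_nested(nest(seq_len(n)), labels)
}

# k-means++ seeding: first center uniform, second weighted by squared
# distance to the first. Returns NULL when fewer than 2 distinct points.
kmeanspp_centers <- function(X) {
  n <- nrow(X)
  c1 <- X[sample.int(n, 1), , drop = FALSE]
  d2 <- rowSums(sweep(X, 2, c1)^2)
  if (sum(d2) <= 0) return(NULL)
  c2 <- X[sample.int(n, 1, prob = d2), , drop = FALSE]
  rbind(c1, c2)
}

#' Recursive 2-means view
#'
#' Divisive, local-geometry view: recursively splits the current item
#' set by 2-means on the working coordinates (the feature matrix `X`
#' when provided -- its natural input -- otherwise the rows of `W`),
#' until singletons remain. Each split runs 10 restarts of k-means++
#' seeded Lloyd iterations and keeps the best inertia; a degenerate
#' split (all points identical, or an empty side) falls back to a
#' balanced index split.
#'
#' @param W similarity matrix.
#' @param X optional numeric feature matrix with one row per item, in
#'   the same order as `W`'s ids.
#' @param seed integer master seed for the k-means restarts.
#' @param n_restarts number of k-means++ restarts per split.
#' @return a [mergetree()].
#' @export
recursive_kmeans_view <- function(W, X = NULL, seed = 1, n_restarts = 10) {
  W <- as_similarity(W)
  coords <- view_coords(W, X)
  counter <- 0L
  split_fun <- function(idx) {
    counter <<- counter + 1L
    Xi <- coords[idx, , drop = FALSE]
    if (nrow(unique(Xi)) < 2L) {
      h <- ceiling(length(idx) / 2)
      return(list(idx[seq_len(h)], idx[-seq_len(h)]))
    }
    best <- NULL
    for (r in seq_len(n_restarts)) {
      km <- with_seed(derive_seed(seed, counter * 1000L + r), {
        ctr <- kmeanspp_centers(Xi)
        if (is.null(ctr)) NULL else {
          tryCatch(suppressWarnings(
            stats::kmeans(Xi, centers = ctr, iter.max = 200,
                          algorithm = "Lloyd")),
            error = function(e) NULL)
        }
      })
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best) || length(unique(best$cluster)) < 2L) {
      h <- ceiling(length(idx) / 2)
      return(list(idx[seq_len(h)], idx[-seq_len(h)]))
    }
    side <- best$cluster == best$cluster[1]
    list(idx[side], idx[!side])
  }
  divisive_tree(nrow(W), rownames(W), split_fun)
}

view_coords <- function(W, X) {
  if (is.null(X)) return(unname(W))
  X <- as.matrix(X)
  if (nrow(X) != nrow(W)) {
    stop("feature matrix has ", nrow(X), " rows but W has ", nrow(W))
  }
  unname(X)
}

#' Centroid-linkage view
#'
#' Agglomerative, geometric view: repeatedly merges the pair of
#' clusters whose centroids (unweighted means of member coordinates)
#' are closest in Euclidean distance; the working coordinates are `X`
#' when provided, otherwise the rows of `W`. Ties are broken by the
#' lexicographic representative rule shared with [average_linkage()].
#'
#' @inheritParams recursive_kmeans_view
#' @return a [mergetree()].
#' @export
centroid_linkage_view <- function(W, X = NULL) {
  W <- as_similarity(W)
  coords <- view_coords(W, X)
  n <- nrow(W)
  cent <- coords
  size <- rep(1L, n)
  repr <- seq_len(n)
  code <- -seq_len(n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2)
  for (m in seq_len(n - 1L)) {
    slots <- which(active)
    D <- as.matrix(stats::dist(cent[slots, , drop = FALSE]))
    ut <- which(upper.tri(D), arr.ind = TRUE)
    i <- slots[ut[, 1]]
    j <- slots[ut[, 2]]
    dd <- D[ut]
    k1 <- pmin(repr[i], repr[j])
    k2 <- pmax(repr[i], repr[j])
    pick <- order(dd, k1, k2)[1]
    a <- i[pick]
    b <- j[pick]
    left_first <- repr[a] <= repr[b]
    merge[m, ] <- if (left_first) c(code[a], code[b]) else c(code[b], code[a])
    cent[a, ] <- (size[a] * cent[a, ] + size[b] * cent[b, ]) /
      (size[a] + size[b])
    size[a] <- size[a] + size[b]
    repr[a] <- min(repr[a], repr[b])
    code[a] <- m
    active[b] <- FALSE
  }
  mergetree(merge, rownames(W))
}

#' Build the standard view set
#'
#' Runs the three structurally diverse views (spectral bisection,
#' recursive 2-means, centroid linkage), converts each dendrogram into
#' a similarity matrix via [tree_to_similarity()], and returns them as
#' a named list in `[0, 1]` sharing `W`'s ids.
#'
#' @inheritParams recursive_kmeans_view
#' @return named list of similarity matrices
#'   (`spectral`, `kmeans`, `centroid`), with the underlying trees in
#'   attribute `"trees"`.
#' @export
build_view_set <- function(W, X = NULL, seed = 1) {
  W <- as_similarity(W)
  if (nrow(W) < 3L) stop("view construction needs at least 3 items")
  trees <- list(
    spectral = laplacian_bisection_view(W),
    kmeans = recursive_kmeans_view(W, X, seed = derive_seed(seed, 21L)),
    centroid = centroid_linkage_view(W, X)
  )
  views <- lapply(trees, tree_to_similarity)
  attr(views, "trees") <- trees
  views
}
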
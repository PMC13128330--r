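#' Blended multi-view hierarchical clustering
#'
#' The full pipeline: derive the selected structural views from `W`,
#' search the blending-parameter space with the surrogate-assisted
#' optimizer, and cluster the best blended matrix with average linkage.
#' With no views (or a `NULL` view selection) the pipeline reduces to
#' plain average linkage on `W`.
#'
#' @param W similarity matrix (see [as_similarity()]).
#' @param X optional feature matrix (rows = items, same order as `W`);
#'   used by the k-means and centroid views.
#' @param views character subset of
#'   `c("spectral", "kmeans", "centroid")`; empty for the identity
#'   reduction.
#' @param variant fitness variant, `"robust"` or `"optimal"` (see
#'   [fitness_spec()]).
#' @param seed master seed.
#' @param budget a [search_budget()].
#' @param B_full,B_cheap bootstrap counts for the robust variant.
#' @return list as returned by [optimize_blend()], plus `views` (the
#'   view matrices used, possibly empty).
#' @export
blend_cluster <- function(W, X = NULL,
                          views = c("spectral", "kmeans", "centroid"),
                          variant = c("robust", "optimal"), seed = 1,
                          budget = search_budget(), B_full = 10,
                          B_cheap = 3) {
  variant <- match.arg(variant)
  W <- as_similarity(W)
  known <- c("spectral", "kmeans", "centroid")
  if (length(views) && !all(views %in% known)) {
    stop("unknown view(s): ", paste(setdiff(views, known), collapse = ", "))
  }
  if (length(views) == 0L) {
    tree <- average_linkage(W)
    cost <- dasgupta_cost(W, tree)
    return(list(params = NULL, tree = tree, cost = cost, fitness = cost,
                baseline_cost = cost, baseline_fitness = cost,
                trace = NULL, views = list()))
  }
  builders <- list(
    spectral = function() laplacian_bisection_view(W),
    kmeans = function() recursive_kmeans_view(W, X,
                                              seed = derive_seed(seed, 21L)),
    centroid = function() centroid_linkage_view(W, X)
  )
  trees <- lapply(builders[views], function(f) f())
  vs <- lapply(trees, tree_to_similarity)
  spec <- fitness_spec(variant = variant, B_full = B_full,
                       B_cheap = B_cheap, seed = seed)
  out <- optimize_blend(W, vs, budget = budget, spec = spec)
  out$views <- vs
  out
}
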
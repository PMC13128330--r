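# Non-trivial clades of a tree as canonical strings (sorted labels);
# clades of size 1 or N carry no topological information.
clade_strings <- function(tree) {
  n <- tree$n_leaves
  sets <- leaf_sets(tree)
  out <- vapply(sets, function(s) {
    paste(sort(tree$labels[s]), collapse = "\r")
  }, character(1))
  sizes <- lengths(sets)
  out[sizes >= 2 & sizes <= n - 1]
}

#' Normalized Robinson-Foulds distance between two dendrograms
#'
#' Counts the non-trivial clades (clusters) present in one tree but not
#' the other and normalizes by the total non-trivial clade count of
#' both trees (`2(n - 2)` for two rooted binary trees), giving a scale
#' from 0 (identical topology) to 1 (no shared clades).
#'
#' @param t1,t2 [mergetree()] objects over the same leaf set.
#' @return value in `[0, 1]`.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$labels, t2$labels)) {
    stop("trees have different leaf sets")
  }
  c1 <- clade_strings(t1)
  c2 <- clade_strings(t2)
  denom <- length(c1) + length(c2)
  if (denom == 0) return(0)  # n = 2: single shared topology
  (sum(!c1 %in% c2) + sum(!c2 %in% c1)) / denom
}

#' Adjusted Rand index between two flat partitions
#'
#' Standard permutation-model chance-corrected agreement; 1 for
#' identical partitions, approximately 0 for independent ones.
#'
#' @param p1,p2 cluster label vectors; if named, items are matched by
#'   name, otherwise by position.
#' @return scalar ARI.
#' @export
ari <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) {
      stop("partitions cover different items")
    }
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stop("partitions have different lengths")
  }
  mclust::adjustedRandIndex(as.vector(p1), as.vector(p2))
}

#' Ground-truth Dasgupta cost of a tree
#'
#' Builds the ground-truth similarity matrix `Wtrue` (1 for items in
#' the same class, 0 otherwise) and returns the tree's Dasgupta cost
#' against it; lower cost means the hierarchy keeps classes in smaller
#' subtrees.
#'
#' @param tree a [mergetree()].
#' @param labels named vector of class labels covering the tree's
#'   leaves.
#' @return non-negative scalar.
#' @export
ground_truth_cost <- function(tree, labels) {
  if (is.null(names(labels))) {
    stop("labels must be named by item id")
  }
  if (!all(tree$labels %in% names(labels))) {
    stop("labels missing for some leaves")
  }
  lab <- as.character(labels[tree$labels])
  Wtrue <- outer(lab, lab, "==") * 1
  diag(Wtrue) <- 0
  dimnames(Wtrue) <- list(tree$labels, tree$labels)
  dasgupta_cost(Wtrue, tree)
}

#' Percent improvement over a baseline cost
#'
#' `100 * (cost_baseline - cost_method) / cost_baseline`; positive
#' means the method attains lower cost than the baseline.
#'
#' @param cost_method cost of the evaluated method.
#' @param cost_baseline cost of the baseline.
#' @return percentage (0 when the baseline cost is 0).
#' @export
improvement_pct <- function(cost_method, cost_baseline) {
  if (cost_baseline == 0) return(0)
  100 * (cost_baseline - cost_method) / cost_baseline
}

#' Rank dendrogram communities by merge separation
#'
#' Each internal node merging sibling communities A and B is scored by
#' a one-sided Mann-Whitney U test of whether the cross distances
#' between A and B are stochastically greater than the within
#' distances of A plus those of B (distances are `1 - S`). Both child
#' communities inherit their merge's p-value; the root carries none.
#' Communities are ranked by ascending p (ties broken by larger
#' community first). A merge of two singletons has no within pairs and
#' gets p = 1 (untestable).
#'
#' @param tree a [mergetree()].
#' @param S similarity matrix used for the distances (e.g. a
#'   correlation-based similarity).
#' @return data frame with one row per non-root internal-node
#'   community: `node` (merge index), `size`, `p`, `rank`, and the
#'   community leaf labels in list column `leaves`.
#' @export
rank_communities <- function(tree, S) {
  S <- as_similarity(S)
  S <- align_similarity(S, tree$labels)
  D <- 1 - S
  n <- tree$n_leaves
  sets <- leaf_sets(tree)
  merge <- tree$merge
  pval <- rep(NA_real_, n - 1L)
  for (m in seq_len(n - 1L)) {
    a <- merge[m, 1]
    b <- merge[m, 2]
    A <- if (a < 0) -a else sets[[a]]
    B <- if (b < 0) -b else sets[[b]]
    within <- c(D[A, A][upper.tri(matrix(0, length(A), length(A)))],
                D[B, B][upper.tri(matrix(0, length(B), length(B)))])
    cross <- as.vector(D[A, B])
    if (length(within) == 0) {
      pval[m] <- 1
    } else if (max(c(cross, within)) - min(c(cross, within)) == 0) {
      pval[m] <- 1  # all distances tied: no dominance is testable
    } else {
      pval[m] <- suppressWarnings(
        stats::wilcox.test(cross, within, alternative = "greater")$p.value
      )
    }
  }
  rows <- list()
  for (m in seq_len(n - 1L)) {  # children of merge m inherit p[m]
    for (ch in merge[m, ]) {
      if (ch > 0) {  # internal, non-root by construction
        rows[[length(rows) + 1L]] <- data.frame(
          node = ch, size = length(sets[[ch]]), p = pval[m]
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p, -out$size, out$node), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$leaves <- I(lapply(out$node, function(m) tree$labels[sets[[m]]]))
  rownames(out) <- NULL
  out
}

set_f1 <- function(a, b) {
  inter <- length(intersect(a, b))
  if (inter == 0) return(0)
  prec <- inter / length(b)
  rec <- inter / length(a)
  2 * prec * rec / (prec + rec)
}

#' Item sets of every ontology term by descendant expansion
#'
#' A term's ground-truth item set contains the items annotated to it or
#' to any of its descendants (equivalently: items whose
#' ancestor-expanded annotations include the term). Terms with no items
#' are dropped.
#'
#' @param ontology ontology list with `parents` (named list
#'   child -> parents) and `terms`.
#' @param annotations named character vector item -> annotated term.
#' @return named list of item-id vectors.
#' @export
ontology_term_sets <- function(ontology, annotations) {
  expand <- lapply(annotations, function(t) {
    c(t, ontology_ancestors(ontology, t))
  })
  terms <- unique(c(ontology$terms, unlist(expand)))
  sets <- lapply(terms, function(t) {
    names(annotations)[vapply(expand, function(e) t %in% e, logical(1))]
  })
  names(sets) <- terms
  sets[lengths(sets) > 0]
}

#' Ancestor-expanded average F1 of top-ranked communities
#'
#' Compares the top `N` ranked communities against the full set of
#' ground-truth term item sets (after descendant expansion, so correct
#' coarse groupings are credited even when fine distinctions are
#' imperfect). The default `"term"` direction averages, over terms, the
#' best-match F1 against the communities (monotone non-decreasing as
#' communities are appended); `"community"` averages over communities,
#' and `"symmetric"` is the mean of the two directions.
#'
#' @param communities list of item-id vectors in rank order.
#' @param ontology,annotations as in [ontology_term_sets()].
#' @param N number of top communities to use.
#' @param direction `"term"`, `"community"` or `"symmetric"`.
#' @return scalar average F1 in `[0, 1]`.
#' @export
ontology_f1 <- function(communities, ontology, annotations, N,
                        direction = c("term", "community", "symmetric")) {
  direction <- match.arg(direction)
  if (N < 1) stop("N must be >= 1")
  comm <- communities[seq_len(min(N, length(communities)))]
  sets <- ontology_term_sets(ontology, annotations)
  if (length(sets) == 0) stop("no ontology term has any item")
  term_best <- vapply(sets, function(ts) {
    max(vapply(comm, function(cc) set_f1(ts, cc), numeric(1)))
  }, numeric(1))
  comm_best <- vapply(comm, function(cc) {
    max(vapply(sets, function(ts) set_f1(ts, cc), numeric(1)))
  }, numeric(1))
  switch(direction,
         term = mean(term_best),
         community = mean(comm_best),
         symmetric = (mean(term_best) + mean(comm_best)) / 2)
}

#' Jaccard bootstrap stability of the k-cut clusters
#'
#' For each cluster of the reference tree's k-cut, the mean (over `B`
#' item subsamples) of its best Jaccard overlap with any cluster
#' obtained by re-clustering the subsample. Values near 1 indicate
#' clusters that survive data perturbation.
#'
#' @param W similarity matrix.
#' @param clusterer function mapping a similarity matrix to a
#'   [mergetree()] (e.g. [average_linkage()]).
#' @param k number of clusters to cut at.
#' @param B number of bootstrap subsamples.
#' @param seed integer seed.
#' @return named numeric vector of per-cluster stabilities.
#' @export
jaccard_stability <- function(W, clusterer, k, B = 20, seed = 1) {
  W <- as_similarity(W)
  if (B < 1) stop("B must be >= 1")
  n <- nrow(W)
  ref_tree <- clusterer(W)
  ref <- cut_tree(ref_tree, k)
  ref_sets <- split(names(ref), ref)
  res <- resample_sets(n, B, derive_seed(seed, 51L))
  stab <- matrix(NA_real_, length(ref_sets), B)
  for (b in seq_len(B)) {
    idx <- res[[b]]
    Wb <- W[idx, idx, drop = FALSE]
    part <- cut_tree(clusterer(Wb), min(k, nrow(Wb)))
    part_sets <- split(names(part), part)
    for (j in seq_along(ref_sets)) {
      rj <- intersect(ref_sets[[j]], rownames(Wb))
      if (length(rj) == 0) next
      stab[j, b] <- max(vapply(part_sets, function(ps) {
        length(intersect(rj, ps)) / length(union(rj, ps))
      }, numeric(1)))
    }
  }
  out <- rowMeans(stab, na.rm = TRUE)
  names(out) <- names(ref_sets)
  out
}
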
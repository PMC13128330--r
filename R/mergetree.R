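#' Rooted binary merge trees
#'
#' A `mergetree` is a rooted binary dendrogram over `N` labeled leaves,
#' stored as an ordered table of `N - 1` merges in the `stats::hclust`
#' convention: row `m` of `$merge` holds the two children of internal
#' node `m`, a negative entry `-i` referring to leaf `i` and a positive
#' entry `j` referring to the internal node created at merge `j < m`.
#' No heights are stored: every computation in this package (Dasgupta
#' cost, tree-to-similarity conversion, Robinson-Foulds distance, cuts)
#' is purely topological, and cuts use merge order instead of heights.
#'
#' @param merge integer `(N-1) x 2` matrix of child references.
#' @param labels character vector of `N` unique leaf identifiers.
#' @return an object of class `mergetree` with fields `merge`, `labels`,
#'   `n_leaves` and `node_size` (leaf counts of the internal nodes, in
#'   merge order).
#' @export
mergetree <- function(merge, labels) {
  merge <- matrix(as.integer(merge), ncol = 2)
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 2L) stop("a mergetree needs at least 2 leaves")
  if (anyDuplicated(labels)) stop("leaf labels must be unique")
  if (nrow(merge) != n - 1L) {
    stop("expected ", n - 1L, " merges for ", n, " leaves, got ", nrow(merge))
  }
  kids <- as.vector(t(merge))
  leaves <- -kids[kids < 0]
  internals <- kids[kids > 0]
  if (any(kids == 0L)) stop("merge table contains a zero child reference")
  if (!setequal(leaves, seq_len(n)) || anyDuplicated(leaves)) {
    stop("each leaf must appear exactly once as a child")
  }
  if (anyDuplicated(internals)) {
    stop("an internal node is used as a child more than once")
  }
  if (!setequal(internals, seq_len(n - 2L))) {
    stop("internal children must be exactly nodes 1..N-2 (root is unused)")
  }
  for (m in seq_len(nrow(merge))) {
    up <- merge[m, ][merge[m, ] > 0]
    if (any(up >= m)) stop("merge row ", m, " references a later node")
  }
  size <- integer(n - 1L)
  for (m in seq_len(n - 1L)) {
    size[m] <- sum(ifelse(merge[m, ] < 0, 1L, size[pmax(merge[m, ], 1L)]))
  }
  structure(
    list(merge = merge, labels = labels, n_leaves = n, node_size = size),
    class = "mergetree"
  )
}

#' @export
print.mergetree <- function(x, ...) {
  cat("mergetree:", x$n_leaves, "leaves,", nrow(x$merge), "merges\n")
  cat("  ", to_newick(x), "\n", sep = "")
  invisible(x)
}

#' Number of leaves of a merge tree
#' @param tree a `mergetree`.
#' @return integer leaf count.
#' @export
n_leaves <- function(tree) tree$n_leaves

# Leaf index sets of every internal node, in merge order.
# Total size over all nodes is O(n^2); fine at package scale.
leaf_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  for (m in seq_len(nrow(tree$merge))) {
    a <- tree$merge[m, 1]
    b <- tree$merge[m, 2]
    sets[[m]] <- c(if (a < 0) -a else sets[[a]],
                   if (b < 0) -b else sets[[b]])
  }
  sets
}

#' Cut a merge tree into k clusters
#'
#' Undoes the last `k - 1` merges (highest merge order first), yielding
#' exactly `k` clusters. This replaces the usual height-based cut, which
#' is unavailable for topology-only trees.
#'
#' @param tree a `mergetree`.
#' @param k integer number of clusters, `1 <= k <= N`.
#' @return named integer vector of cluster labels `1..k` (names are leaf
#'   labels); clusters are numbered by first appearance in leaf order.
#' @export
cut_tree <- function(tree, k) {
  n <- tree$n_leaves
  if (length(k) != 1L || is.na(k) || k < 1 || k > n) {
    stop("k must be in [1, ", n, "]")
  }
  k <- as.integer(k)
  sets <- leaf_sets(tree)
  comp <- seq_len(n)
  for (m in seq_len(n - k)) {  # apply all but the last k-1 merges
    s <- sets[[m]]
    comp[comp %in% comp[s]] <- comp[s[1]]
  }
  ids <- unique(comp)
  out <- match(comp, ids)
  names(out) <- tree$labels
  out
}

#' Serialize a merge tree to Newick
#'
#' Topology-only Newick: leaf labels verbatim, no branch lengths.
#'
#' @param tree a `mergetree`.
#' @return a single Newick string terminated by `;`.
#' @export
to_newick <- function(tree) {
  n <- tree$n_leaves
  str <- character(n - 1L)
  for (m in seq_len(n - 1L)) {
    ch <- vapply(tree$merge[m, ], function(x) {
      if (x < 0) tree$labels[-x] else str[x]
    }, character(1))
    str[m] <- paste0("(", ch[1], ",", ch[2], ")")
  }
  paste0(str[n - 1L], ";")
}

#' Merge-table serialization
#'
#' The exchange format for trees is a table with columns `node_id`,
#' `left_child`, `right_child`, `order`: internal nodes are named
#' `N1..N(n-1)` in merge order and children are either leaf labels or
#' earlier node ids.
#'
#' @param tree a `mergetree`.
#' @return a data frame with one row per merge.
#' @export
to_merge_table <- function(tree) {
  ref <- function(x) if (x < 0) tree$labels[-x] else paste0("N", x)
  data.frame(
    node_id = paste0("N", seq_len(nrow(tree$merge))),
    left_child = vapply(tree$merge[, 1], ref, character(1)),
    right_child = vapply(tree$merge[, 2], ref, character(1)),
    order = seq_len(nrow(tree$merge)),
    stringsAsFactors = FALSE
  )
}

#' Rebuild a merge tree from a merge table
#'
#' Children must reference either leaf labels or previously defined node
#' ids; forward references and reused children are parse errors.
#'
#' @param tab data frame as produced by [to_merge_table()].
#' @return a `mergetree`.
#' @export
from_merge_table <- function(tab) {
  need <- c("node_id", "left_child", "right_child", "order")
  if (!all(need %in% names(tab))) {
    stop("merge table must have columns ", paste(need, collapse = ", "))
  }
  tab <- tab[order(tab$order), , drop = FALSE]
  node_ids <- as.character(tab$node_id)
  if (anyDuplicated(node_ids)) stop("duplicate node_id in merge table")
  kids <- c(as.character(tab$left_child), as.character(tab$right_child))
  leaf_names <- setdiff(kids, node_ids)
  if (anyDuplicated(kids)) {
    stop("child '", kids[duplicated(kids)][1],
         "' is referenced more than once")
  }
  # preserve first-appearance order of leaves
  leaves <- kids[kids %in% leaf_names]
  leaves <- leaves[order(match(leaves, kids))]
  m <- matrix(0L, nrow(tab), 2)
  for (r in seq_len(nrow(tab))) {
    for (s in 1:2) {
      ch <- as.character(tab[[c("left_child", "right_child")[s]]][r])
      if (ch %in% leaves) {
        m[r, s] <- -match(ch, leaves)
      } else {
        j <- match(ch, node_ids)
        if (is.na(j) || j >= r) {
          stop("child '", ch, "' in row ", r,
               " is a forward or unknown node reference")
        }
        m[r, s] <- j
      }
    }
  }
  mergetree(m, leaves)
}

#' Generate a random merge tree
#'
#' Repeatedly merges two uniformly chosen active clusters; used for
#' property tests and null models.
#'
#' @param n number of leaves.
#' @param seed integer seed.
#' @param labels optional leaf labels (default `item001...`).
#' @return a `mergetree`.
#' @export
random_mergetree <- function(n, seed = 1, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("item%03d", seq_len(n))
  with_seed(seed, {
    code <- -seq_len(n)
    merge <- matrix(0L, n - 1L, 2)
    for (m in seq_len(n - 1L)) {
      pick <- sample(length(code), 2)
      merge[m, ] <- code[pick]
      code <- c(code[-pick], m)
    }
    mergetree(merge, labels)
  })
}

# Build a mergetree from a nested structure of leaf indices:
# a node is either a single integer (leaf) or list(left, right).
tree_from_nested <- function(node, labels) {
  n <- length(labels)
  merge <- matrix(0L, n - 1L, 2)
  row <- 0L
  build <- function(nd) {
    if (!is.list(nd)) return(-as.integer(nd))
    l <- build(nd[[1]])
    r <- build(nd[[2]])
    row <<- row + 1L
    merge[row, ] <<- c(l, r)
    row
  }
  build(node)
  mergetree(merge, labels)
}

# Nested balanced topology over a vector of leaf indices, or over a
# list of already-nested subtrees (joined balanced).
balanced_nested <- function(idx) {
  if (length(idx) == 1L) {
    return(if (is.list(idx)) idx[[1]] else idx[1])
  }
  h <- ceiling(length(idx) / 2)
  list(balanced_nested(idx[seq_len(h)]),
       balanced_nested(idx[-seq_len(h)]))
}
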
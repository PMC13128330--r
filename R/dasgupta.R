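#' Dasgupta cost of a dendrogram
#'
#' The cost of a rooted binary tree `T` for a similarity matrix `W` is
#' `sum over unordered pairs i < j of Wij * |Tij|`, where `|Tij|` is the
#' number of leaves of the smallest subtree containing both `i` and `j`.
#' Pairs with high similarity should be merged early (small subtrees);
#' the minimizer of this objective defines an optimal hierarchy.
#'
#' Computed in a single bottom-up sweep: the internal node merging leaf
#' sets `L` and `R` is the LCA of exactly the `|L| * |R|` cross pairs,
#' each with subtree size `|L| + |R|`. Summed over all merges the cross
#' blocks cover each pair once, so the sweep is O(n^2) overall.
#'
#' @param W similarity matrix (see [as_similarity()]); its ids must be a
#'   permutation of the tree's leaf labels.
#' @param tree a [mergetree()].
#' @return non-negative scalar cost.
#' @export
dasgupta_cost <- function(W, tree) {
  W <- as_similarity(W)
  W <- align_similarity(W, tree$labels)
  merge <- tree$merge
  n <- tree$n_leaves
  sets <- vector("list", n - 1L)
  cost <- 0
  for (m in seq_len(n - 1L)) {
    a <- merge[m, 1]
    b <- merge[m, 2]
    A <- if (a < 0) -a else sets[[a]]
    B <- if (b < 0) -b else sets[[b]]
    cost <- cost + sum(W[A, B]) * (length(A) + length(B))
    sets[[m]] <- c(A, B)
  }
  cost
}

#' Convert a dendrogram back into a similarity matrix
#'
#' For every leaf pair `(i, j)` the derived similarity is
#' `S'ij = (N - |Tij|) / (N - 2)`: sibling leaves (`|Tij| = 2`) map to 1,
#' pairs whose LCA is the root (`|Tij| = N`) map to 0, so all values lie
#' in `[0, 1]`. This is how alternative structural views re-enter the
#' blending stage as similarity matrices.
#'
#' @param tree a [mergetree()] with `N >= 3` leaves.
#' @return an `N x N` similarity matrix with the tree's labels as ids.
#' @export
tree_to_similarity <- function(tree) {
  n <- tree$n_leaves
  if (n < 3L) stop("tree-to-similarity conversion needs N >= 3 leaves ",
                   "(denominator N - 2)")
  merge <- tree$merge
  S <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  sets <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    a <- merge[m, 1]
    b <- merge[m, 2]
    A <- if (a < 0) -a else sets[[a]]
    B <- if (b < 0) -b else sets[[b]]
    S[A, B] <- (n - (length(A) + length(B))) / (n - 2)
    sets[[m]] <- c(A, B)
  }
  S <- pmax(S, t(S))
  diag(S) <- 0
  S
}

#' Exact minimum-cost tree by dynamic programming over subsets
#'
#' Test oracle for the NP-hard objective: computes the exact optimum of
#' the Dasgupta cost by memoized dynamic programming over item subsets,
#' `cost(S) = min over splits S = A | B of cost(A) + cost(B) + |S| * W(A, B)`.
#' Feasible only for small n (3^n subset-split pairs); guarded at
#' `n <= 10`.
#'
#' @param W similarity matrix.
#' @param max_n size guard (default 10).
#' @return list with elements `tree` (an optimal [mergetree()]) and
#'   `cost` (its Dasgupta cost).
#' @export
optimal_tree_bruteforce <- function(W, max_n = 10) {
  W <- as_similarity(W)
  n <- nrow(W)
  if (n > max_n) {
    stop("exact search is limited to n <= ", max_n, " items (got ", n, ")")
  }
  npow <- bitwShiftL(1L, n)
  full <- npow - 1L
  bitof <- bitwShiftL(1L, seq_len(n) - 1L)

  # cross[i, S+1] = sum_{j in S} W[i, j], built incrementally
  cross <- matrix(0, n, npow)
  for (S in 1:full) {
    low <- (1:n)[bitwAnd(S, bitof) != 0][1]
    R <- S - bitof[low]
    cross[, S + 1L] <- cross[, R + 1L] + W[, low]
  }
  # pairsum[S+1] = total weight of pairs within S
  pairsum <- numeric(npow)
  popcnt <- integer(npow)
  for (S in 1:full) {
    low <- (1:n)[bitwAnd(S, bitof) != 0][1]
    R <- S - bitof[low]
    pairsum[S + 1L] <- pairsum[R + 1L] + cross[low, R + 1L]
    popcnt[S + 1L] <- popcnt[R + 1L] + 1L
  }

  best <- rep(Inf, npow)
  split <- integer(npow)
  best[bitof + 1L] <- 0
  for (S in 1:full) {
    sz <- popcnt[S + 1L]
    if (sz < 2L) next
    low <- bitof[(1:n)[bitwAnd(S, bitof) != 0][1]]
    # enumerate halves A containing the lowest bit (canonical split)
    A <- S
    bst <- Inf
    arg <- 0L
    repeat {
      A <- bitwAnd(A - 1L, S)
      if (A == 0L) break
      if (bitwAnd(A, low) == 0L) next
      B <- S - A
      cr <- pairsum[S + 1L] - pairsum[A + 1L] - pairsum[B + 1L]
      v <- best[A + 1L] + best[B + 1L] + cr * sz
      if (v < bst) {
        bst <- v
        arg <- A
      }
    }
    best[S + 1L] <- bst
    split[S + 1L] <- arg
  }

  nested <- function(S) {
    if (popcnt[S + 1L] == 1L) return((1:n)[bitof == S])
    A <- split[S + 1L]
    list(nested(A), nested(S - A))
  }
  tree <- tree_from_nested(nested(full), rownames(W))
  list(tree = tree, cost = best[npow])
}
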
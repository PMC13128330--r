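# Shared agglomerative state helpers.
#
# Active clusters live in "slots" 1..n. `S` is the matrix of summed
# cross-similarities between slots, `size` the cluster sizes, `repr`
# the smallest original leaf index in each cluster (used for the global
# deterministic tie rule: among equal-score pairs, merge the pair with
# the lexicographically smallest (min repr, max repr)).

# Rank candidate merges by average similarity (descending), ties broken
# by the lexicographic representative rule. Returns up to `top_m` rows
# with slot indices i < j and the average similarity.
ranked_pairs <- function(S, size, repr, active, top_m = 1L) {
  slots <- which(active)
  A <- S[slots, slots, drop = FALSE] /
    outer(size[slots], size[slots])
  ut <- which(upper.tri(A), arr.ind = TRUE)
  avg <- A[ut]
  i <- slots[ut[, 1]]
  j <- slots[ut[, 2]]
  k1 <- pmin(repr[i], repr[j])
  k2 <- pmax(repr[i], repr[j])
  ord <- order(-avg, k1, k2)
  take <- ord[seq_len(min(top_m, length(ord)))]
  cbind(i = i[take], j = j[take], avg = avg[take])
}

# Apply one merge to agglomerative state; returns the updated state.
# The new cluster occupies slot i; slot j is retired. The merge row is
# recorded with the smaller-representative child on the left.
apply_merge <- function(st, i, j, m) {
  left_first <- st$repr[i] <= st$repr[j]
  st$merge[m, ] <- if (left_first) c(st$code[i], st$code[j]) else
    c(st$code[j], st$code[i])
  st$S[i, ] <- st$S[i, ] + st$S[j, ]
  st$S[, i] <- st$S[, i] + st$S[, j]
  st$S[i, i] <- 0
  st$size[i] <- st$size[i] + st$size[j]
  st$repr[i] <- min(st$repr[i], st$repr[j])
  st$active[j] <- FALSE
  st$code[i] <- m
  st
}

new_agglo_state <- function(W) {
  n <- nrow(W)
  list(
    S = unname(W), size = rep(1L, n), repr = seq_len(n),
    code = -seq_len(n), active = rep(TRUE, n),
    merge = matrix(0L, n - 1L, 2)
  )
}

#' Average-linkage clustering on a similarity matrix
#'
#' Agglomerative clustering that repeatedly merges the pair of clusters
#' with the maximum average pairwise similarity (unweighted mean over
#' all cross-pairs of original entries). It operates natively on
#' similarities -- no similarity-to-distance transform -- and is the
#' final-stage algorithm applied to every blended matrix. Ties are
#' broken deterministically toward the pair with the lexicographically
#' smallest (min leaf index, max leaf index) of cluster representatives.
#'
#' @param W similarity matrix (see [as_similarity()]).
#' @return a [mergetree()].
#' @export
average_linkage <- function(W) {
  W <- as_similarity(W)
  n <- nrow(W)
  st <- new_agglo_state(W)
  for (m in seq_len(n - 1L)) {
    p <- ranked_pairs(st$S, st$size, st$repr, st$active, 1L)
    st <- apply_merge(st, p[1, "i"], p[1, "j"], m)
  }
  mergetree(st$merge, rownames(W))
}
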
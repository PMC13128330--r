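# Independent oracles used across the suite. These deliberately use
# naive O(n^3) formulations so they share no code path with the
# package's O(n^2) implementations.

# random symmetric non-negative similarity with ids
random_similarity <- function(n, seed) {
  withr::with_seed(seed, {
    M <- matrix(stats::runif(n * n), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    as_similarity(M)
  })
}

# Dasgupta cost by per-pair LCA search: for each pair scan the merge
# list for the first (smallest) cluster containing both leaves.
naive_dasgupta <- function(W, tree) {
  W <- align_similarity(W, tree$labels)
  n <- tree$n_leaves
  sets <- dendroblend:::leaf_sets(tree)
  cost <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      for (m in seq_along(sets)) {
        if (i %in% sets[[m]] && j %in% sets[[m]]) {
          cost <- cost + W[i, j] * length(sets[[m]])
          break
        }
      }
    }
  }
  cost
}

# Textbook UPGMA on similarities: recompute every cluster-pair average
# from the original matrix at every step, merge the maximum, ties by
# the lexicographic (min leaf, max leaf) representative rule.
naive_average_linkage <- function(W) {
  n <- nrow(W)
  clusters <- as.list(seq_len(n))
  code <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2)
  for (m in seq_len(n - 1L)) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        avg <- mean(W[clusters[[a]], clusters[[b]]])
        # representative = smallest original member index
        key <- c(-avg,
                 min(min(clusters[[a]]), min(clusters[[b]])),
                 max(min(clusters[[a]]), min(clusters[[b]])))
        if (is.null(best) || lex_less(key, best$key)) {
          best <- list(a = a, b = b, key = key)
        }
      }
    }
    a <- best$a
    b <- best$b
    left_first <- min(clusters[[a]]) <= min(clusters[[b]])
    merge[m, ] <- if (left_first) c(code[a], code[b]) else c(code[b], code[a])
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    code[a] <- m
    clusters[[b]] <- NULL
    code <- code[-b]
  }
  mergetree(merge, rownames(W))
}

lex_less <- function(x, y) {
  for (i in seq_along(x)) {
    if (x[i] < y[i]) return(TRUE)
    if (x[i] > y[i]) return(FALSE)
  }
  FALSE
}

# all rooted binary topologies on leaves 1..n as unique clade-set
# signatures, with one representative tree each
enumerate_topologies <- function(n, labels = letters[seq_len(n)]) {
  seqs <- list()
  recurse <- function(nested) {
    if (length(nested) == 1L) {
      seqs[[length(seqs) + 1L]] <<- nested[[1]]
      return(invisible())
    }
    for (a in seq_along(nested)) {
      for (b in seq_along(nested)) {
        if (b <= a) next
        nxt <- nested[-c(a, b)]
        nxt[[length(nxt) + 1L]] <- list(nested[[a]], nested[[b]])
        recurse(nxt)
      }
    }
  }
  recurse(as.list(seq_len(n)))
  trees <- lapply(seqs, dendroblend:::tree_from_nested, labels = labels)
  sig <- vapply(trees, function(t) {
    paste(sort(dendroblend:::clade_strings(t)), collapse = "|")
  }, character(1))
  trees[!duplicated(sig)]
}

# clade sets as sorted label strings, computed here independently
clades_of <- function(tree) {
  sets <- dendroblend:::leaf_sets(tree)
  sort(vapply(sets, function(s) {
    paste(sort(tree$labels[s]), collapse = "/")
  }, character(1)))
}

params_to_vector_q <- dendroblend:::params_to_vector
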
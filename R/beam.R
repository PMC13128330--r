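#' Beam search over average-linkage merge sequences
#'
#' Breadth-limited search baseline: at each of the `n - 1` merge steps
#' a beam of the most promising partial clusterings is kept. Every
#' state expands its `max_rank` best next merges under the
#' average-linkage criterion (maximum average similarity); duplicate
#' partial clusterings reached by different merge orders are collapsed,
#' and the pool is pruned back to `beam_width` states. States are
#' ordered by a lexicographic score: primary key the cumulative merge
#' score (sum over performed merges of `1 - avg/max(W)`, i.e. low
#' cumulative linkage cost first), secondary key the sum of chosen
#' merge ranks (sequences of high-ranked merges first), final tie the
#' canonical partition fingerprint. After the last merge, the full
#' Dasgupta cost of every surviving complete tree is computed and the
#' cheapest is returned.
#'
#' With `beam_width = 1, max_rank = 1` the search reduces bit-for-bit
#' to [average_linkage()].
#'
#' @param W similarity matrix.
#' @param beam_width number of states kept per step (>= 1).
#' @param max_rank number of top merges expanded per state (>= 1).
#' @return a [mergetree()].
#' @export
beam_search <- function(W, beam_width = 100, max_rank = 5) {
  W <- as_similarity(W)
  if (beam_width < 1 || max_rank < 1) {
    stop("beam_width and max_rank must be >= 1")
  }
  n <- nrow(W)
  maxW <- max(W)
  st0 <- new_agglo_state(W)
  st0$memb <- seq_len(n)
  st0$cum <- 0
  st0$ranksum <- 0L
  beam <- list(st0)
  for (m in seq_len(n - 1L)) {
    pool <- list()
    key <- character(0)
    for (st in beam) {
      cand <- ranked_pairs(st$S, st$size, st$repr, st$active, max_rank)
      for (q in seq_len(nrow(cand))) {
        ch <- apply_merge(st, cand[q, "i"], cand[q, "j"], m)
        ch$memb[ch$memb == cand[q, "j"]] <- cand[q, "i"]
        ch$cum <- st$cum +
          if (maxW > 0) 1 - cand[q, "avg"] / maxW else 0
        ch$ranksum <- st$ranksum + q
        fp <- paste(match(ch$memb, unique(ch$memb)), collapse = ",")
        ch$fp <- fp
        hit <- match(fp, key)
        if (is.na(hit)) {
          pool[[length(pool) + 1L]] <- ch
          key <- c(key, fp)
        } else if (ch$cum < pool[[hit]]$cum ||
                   (ch$cum == pool[[hit]]$cum &&
                    ch$ranksum < pool[[hit]]$ranksum)) {
          pool[[hit]] <- ch
        }
      }
    }
    cums <- vapply(pool, `[[`, numeric(1), "cum")
    ranks <- vapply(pool, `[[`, numeric(1), "ranksum")
    fps <- vapply(pool, `[[`, character(1), "fp")
    keep <- order(cums, ranks, fps)[seq_len(min(beam_width, length(pool)))]
    beam <- pool[keep]
  }
  trees <- lapply(beam, function(st) mergetree(st$merge, rownames(W)))
  costs <- vapply(trees, function(tr) dasgupta_cost(W, tr), numeric(1))
  best <- trees[[which.min(costs)]]
  # the greedy merge sequence always survives as a candidate, so the
  # search can never end worse than plain average linkage
  greedy <- average_linkage(W)
  if (dasgupta_cost(W, greedy) < min(costs)) greedy else best
}
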
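test_that("RF distance spans 0 to 1 on the forced cases", {
  t1 <- random_mergetree(8, seed = 1)
  expect_equal(rf_distance(t1, t1), 0)
  cherries_ab <- dendroblend:::tree_from_nested(list(list(1, 2), list(3, 4)),
                                                letters[1:4])
  cherries_ac <- dendroblend:::tree_from_nested(list(list(1, 3), list(2, 4)),
                                                letters[1:4])
  expect_equal(rf_distance(cherries_ab, cherries_ac), 1)
  expect_error(rf_distance(t1, random_mergetree(8, 2, LETTERS[1:8])),
               "leaf sets")
})

test_that("RF on a caterpillar one-swap neighbor matches hand clades", {
  cat1 <- dendroblend:::tree_from_nested(
    list(list(list(list(1, 2), 3), 4), 5), letters[1:5])
  cat2 <- dendroblend:::tree_from_nested(
    list(list(list(list(1, 3), 2), 4), 5), letters[1:5])
  # clade sets {ab, abc, abcd} vs {ac, abc, abcd}: symmetric difference 2
  expect_equal(rf_distance(cat1, cat2), 2 / 6)
})

test_that("RF behaves as a pseudo-metric on seeded triples", {
  for (s in 1:5) {
    ts <- lapply(1:3, function(i) random_mergetree(10, seed = 10 * s + i))
    d12 <- rf_distance(ts[[1]], ts[[2]])
    d13 <- rf_distance(ts[[1]], ts[[3]])
    d23 <- rf_distance(ts[[2]], ts[[3]])
    expect_equal(d12, rf_distance(ts[[2]], ts[[1]]))
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("ARI matches the closed-form on a hand contingency table", {
  expect_equal(ari(rep(1, 4), rep(2, 4)), 1)
  expect_equal(ari(1:6, rep(1, 6)), 0)  # singletons vs one cluster
  # contingency {{2,0},{1,3}}: sums C(.,2): index 4, rows 7, cols 6, tot 15
  p1 <- c("A", "A", "B", "B", "B", "B")
  p2 <- c("X", "X", "X", "Y", "Y", "Y")
  expected <- (4 - 7 * 6 / 15) / ((7 + 6) / 2 - 7 * 6 / 15)
  expect_equal(ari(p1, p2), expected)
  expect_error(ari(stats::setNames(1:3, letters[1:3]),
                   stats::setNames(1:3, letters[2:4])), "different items")
})

test_that("ARI of independent random partitions concentrates near 0", {
  vals <- vapply(1:200, function(i) {
    withr::with_seed(70000 + i,
                     ari(sample(1:4, 50, TRUE), sample(1:4, 50, TRUE)))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("ground-truth cost prefers class-respecting trees", {
  labels <- stats::setNames(rep(c("u", "v"), each = 4),
                            sprintf("item%03d", 1:8))
  # tree whose two clades are the classes vs one splitting a class at root
  good <- dendroblend:::tree_from_nested(
    list(dendroblend:::balanced_nested(1:4),
         dendroblend:::balanced_nested(5:8)), names(labels))
  bad <- dendroblend:::tree_from_nested(
    list(dendroblend:::balanced_nested(c(1, 2, 3, 5)),
         dendroblend:::balanced_nested(c(4, 6, 7, 8))), names(labels))
  expect_lt(ground_truth_cost(good, labels), ground_truth_cost(bad, labels))
  # all-distinct labels make Wtrue vanish
  expect_equal(ground_truth_cost(good,
                                 stats::setNames(letters[1:8],
                                                 names(labels))), 0)
})

test_that("percent improvement follows the sign convention", {
  expect_equal(improvement_pct(80, 100), 20)
  expect_equal(improvement_pct(100, 100), 0)
  expect_equal(improvement_pct(110, 100), -10)
  expect_equal(improvement_pct(5, 0), 0)
})

test_that("community ranking flags separated siblings and ties", {
  ds <- generate_dataset("spherical", 24, seed = 6, k = 2)
  S <- gaussian_kernel_similarity(ds$X)
  tree <- average_linkage(S)
  rc <- rank_communities(tree, S)
  expect_equal(rc$rank, seq_len(nrow(rc)))
  expect_true(all(rc$p >= 0 & rc$p <= 1))
  # the two blob communities merged at the root are highly significant
  top2 <- rc[rc$size == max(rc$size), ]
  expect_lt(top2$p[1], 0.01)

  # all-identical distances are untestable: p = 1 everywhere
  n <- 6
  Sflat <- as_similarity(matrix(0.4, n, n) - diag(0.4, n))
  rc2 <- rank_communities(random_mergetree(n, 3, rownames(Sflat)), Sflat)
  expect_true(all(rc2$p == 1))
})

test_that("ontology F1 handles exact, disjoint and diluted communities", {
  ont <- synthetic_ontology(depth = 2, branching = 2, n_items = 30,
                            seed = 4, extra_parents = 0)
  sets <- ontology_term_sets(ont$ontology, ont$annotations)
  expect_equal(ontology_f1(unname(sets), ont$ontology, ont$annotations,
                           N = length(sets)), 1)
  expect_equal(ontology_f1(unname(sets), ont$ontology, ont$annotations,
                           N = length(sets), direction = "symmetric"), 1)
  expect_equal(ontology_f1(list(c("ghost1", "ghost2")), ont$ontology,
                           ont$annotations, N = 1), 0)

  # full term set plus an equal number of extras: precision 1/2, recall 1
  one_term <- sets[[which(lengths(sets) == max(lengths(sets)))[1]]]
  diluted <- c(one_term, paste0("ghost", seq_along(one_term)))
  simple_ont <- list(parents = list(), terms = "A")
  ann <- stats::setNames(rep("A", length(one_term)), one_term)
  expect_equal(ontology_f1(list(diluted), simple_ont, ann, N = 1), 2 / 3)
})

test_that("term-direction F1 is monotone as communities are appended", {
  ont <- synthetic_ontology(depth = 3, branching = 2, n_items = 40,
                            seed = 8)
  comms <- withr::with_seed(77, lapply(1:8, function(i) {
    sample(names(ont$annotations), sample(3:12, 1))
  }))
  f1s <- vapply(seq_along(comms), function(N) {
    ontology_f1(comms, ont$ontology, ont$annotations, N = N)
  }, numeric(1))
  expect_true(all(diff(f1s) >= -1e-12))
})

test_that("Jaccard stability is 1 for a data-ignoring fixed partition", {
  W <- random_similarity(20, 13)
  fixed_clusterer <- function(M) {
    ids <- rownames(M)
    grp <- as.integer(sub("item", "", ids)) <= 10
    dendroblend:::tree_from_nested(
      list(dendroblend:::balanced_nested(which(grp)),
           dendroblend:::balanced_nested(which(!grp))), ids)
  }
  stab <- jaccard_stability(W, fixed_clusterer, k = 2, B = 5, seed = 1)
  expect_equal(unname(stab), c(1, 1))
})

test_that("well-separated blobs are bootstrap-stable", {
  ds <- generate_dataset("spherical", 40, seed = 5, k = 4)
  S <- gaussian_kernel_similarity(ds$X)
  stab <- jaccard_stability(S, average_linkage, k = 4, B = 20, seed = 2)
  expect_true(all(stab >= 0.8))
})
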
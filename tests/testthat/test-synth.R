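test_that("generators emit matching shapes deterministically", {
  for (type in c("irregular", "spherical", "nonconvex", "nested",
                 "discrete")) {
    d1 <- generate_dataset(type, 30, seed = 11)
    d2 <- generate_dataset(type, 30, seed = 11)
    expect_identical(d1, d2)
    expect_equal(nrow(d1$X), 30)
    expect_length(d1$labels, 30)
    expect_named(d1$labels, rownames(d1$X))
    if (type == "nested") {
      expect_length(d1$hierarchy, 30)
    } else {
      expect_null(d1$hierarchy)
    }
  }
  expect_error(generate_dataset("bogus", 20), "unknown generator")
  expect_error(generate_dataset("spherical", 3), "at least 4")
})

test_that("well-separated spherical clusters are recovered exactly", {
  ds <- generate_dataset("spherical", 40, seed = 5, k = 4)
  S <- gaussian_kernel_similarity(ds$X)
  part <- cut_tree(average_linkage(S), 4)
  expect_equal(ari(part, ds$labels), 1)
})

test_that("discrete data plants exact similarity ties", {
  ds <- generate_dataset("discrete", 24, seed = 3)
  S <- hamming_similarity(ds$X)
  vals <- S[upper.tri(S)]
  expect_gt(sum(vals == 1), 1)  # two prototype-copy pairs tie at 1
  expect_true(anyDuplicated(vals) > 0)
})

test_that("nested hierarchy paths cut to the super-cluster partition", {
  ds <- generate_dataset("nested", 36, seed = 9)
  super <- sub("/.*", "", ds$hierarchy)
  fine <- sub(".*/", "", ds$hierarchy)
  expect_equal(unname(fine), unname(ds$labels))
  # each fine label nests under exactly one coarse label
  expect_true(all(tapply(super, fine, function(x) length(unique(x))) == 1))
})

test_that("decoy instance has the prescribed clique structure", {
  d <- decoy_cliques(2, s = 1, eps = 0.1)
  expect_equal(nrow(d$W), 8)
  vals <- sort(unique(d$W[d$W > 0]))
  expect_equal(vals, c(1, 1.1))
  # 4 decoy pairs at s+eps, 2 optimal 4-cliques at s
  expect_equal(sum(d$W == 1.1) / 2, 4)
  expect_equal(sum(d$W == 1) / 2, 2 * choose(4, 2))
  expect_error(decoy_cliques(1), "kappa")
})

test_that("decoy cost chain: oracle <= column reference < average linkage", {
  d <- decoy_cliques(2, s = 1, eps = 0.1)
  oracle <- optimal_tree_bruteforce(d$W)$cost
  ref <- dasgupta_cost(d$W, d$reference)
  avg <- dasgupta_cost(d$W, average_linkage(d$W))
  expect_lte(oracle, ref + 1e-9)
  expect_lt(ref, avg)
  d3 <- decoy_cliques(3)
  expect_lt(dasgupta_cost(d3$W, d3$reference),
            dasgupta_cost(d3$W, average_linkage(d3$W)))
})

test_that("average linkage is deceived into a decoy row first", {
  d <- decoy_cliques(3)
  first <- dendroblend:::leaf_sets(average_linkage(d$W))[[1]]
  expect_equal(unname(d$row[first[1]]), unname(d$row[first[2]]))
})

test_that("Gaussian kernel follows the median-bandwidth rule", {
  X <- matrix(c(0, 1, 2), ncol = 1)
  S <- gaussian_kernel_similarity(X)  # median distance of {1,1,2} is 1
  expect_equal(S[1, 2], exp(-1 / 2))
  expect_equal(S[2, 3], exp(-1 / 2))
  expect_equal(S[1, 3], exp(-2))
  X0 <- matrix(c(1, 1), ncol = 1)
  expect_error(gaussian_kernel_similarity(X0), "positive")
  # duplicate points at positive bandwidth hit similarity 1
  S2 <- gaussian_kernel_similarity(matrix(c(0, 0, 5), ncol = 1))
  expect_equal(S2[1, 2], 1)
})

test_that("Hamming similarity counts mismatched features", {
  X <- rbind(rep("a", 16), c(rep("a", 12), rep("b", 4)))
  expect_equal(hamming_similarity(X)[1, 2], 0.75)
  expect_equal(hamming_similarity(rbind(c("a", "b"), c("a", "b")))[1, 2], 1)
  expect_equal(hamming_similarity(rbind(c("a", "b"), c("c", "d")))[1, 2], 0)
  expect_error(hamming_similarity(matrix(nrow = 2, ncol = 0)), "feature")
})

test_that("synthetic ontology is a rooted DAG with sane geometry", {
  ont <- synthetic_ontology(depth = 3, branching = 2, n_items = 40,
                            seed = 2, extra_parents = 0)
  # no extra parents: every term has exactly one parent (a tree)
  expect_true(all(lengths(ont$ontology$parents) == 1))
  # ancestor expansion of any annotation reaches the root
  expect_true(all(vapply(ont$annotations, function(t) {
    "T" %in% ontology_ancestors(ont$ontology, t)
  }, logical(1))))

  ont2 <- synthetic_ontology(depth = 3, branching = 2, n_items = 40,
                             seed = 2, extra_parents = 2)
  expect_gte(sum(lengths(ont2$ontology$parents)),
             length(ont2$ontology$parents) + 1)

  # sibling terms are closer in feature space than distant terms
  ann <- ont$annotations
  D <- as.matrix(stats::dist(ont$X))
  parent_of <- function(t) ont$ontology$parents[[t]][1]
  same_parent <- outer(vapply(ann, parent_of, character(1)),
                       vapply(ann, parent_of, character(1)), "==")
  diff_term <- outer(ann, ann, "!=")
  ut <- upper.tri(D)
  near <- D[same_parent & diff_term & ut]
  far <- D[!same_parent & ut]
  expect_lt(mean(near), mean(far))
})
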
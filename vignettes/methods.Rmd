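---
title: "Methods: multi-view similarity blending for hierarchical clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view similarity blending for hierarchical clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroblend)
```

## The objective

Given a symmetric non-negative similarity matrix $W$ over $n$ items,
the quality of a rooted binary dendrogram $T$ is measured by
Dasgupta's cost
$$\mathrm{Cost}(T) = \sum_{i<j} W_{ij}\,|T_{ij}|,$$
where $|T_{ij}|$ is the leaf count of the smallest subtree containing
both $i$ and $j$. Similar pairs should be merged early (small
subtrees). Minimizing the cost is NP-hard; average linkage — merge the
cluster pair with the highest mean pairwise similarity — is a strong
greedy baseline but is sensitive to strong local similarities and
blind to global structure.

Everything in this package is topology-only. Dendrograms
(`mergetree`) store an ordered merge table and no heights: the cost,
the tree-to-similarity conversion, Robinson–Foulds comparison and cuts
never use heights, and `cut_tree(T, k)` undoes the last $k-1$ merges
instead of cutting at a height. The diagonal of every similarity
matrix is defined as ignored and stored as zero — the objective sums
over unordered pairs only, so self-similarity has no meaning here.
The cost is computed in one bottom-up sweep: the node merging leaf
sets $L$ and $R$ is the LCA of exactly its $|L||R|$ cross pairs, each
with subtree size $|L|+|R|$; summed over all merges these blocks
partition the pairs, so the sweep is $O(n^2)$. This matters because
the optimizer evaluates the cost thousands of times.

## Structural views

Three algorithms with different inductive biases are run on $W$:

* **Spectral bisection** (global, graph-based): recursively compute
  the Fiedler vector of the symmetric normalized Laplacian
  $I - D^{-1/2} W D^{-1/2}$, sort items by their entry and split at
  the largest consecutive gap. The normalized Laplacian is the
  standard choice for weighted similarity graphs. Disconnected blocks
  are split component-first (the component of the smallest index
  versus the rest), and an all-zero block falls back to a balanced
  index split. The Fiedler vector's sign is fixed (first non-zero
  entry positive) and gap ties are broken toward the more balanced
  split, then toward the smaller index, so the view is deterministic.
* **Recursive 2-means** (divisive, local geometry): recursively split
  by 2-means, using the feature matrix when one is supplied (its
  natural input) and the rows of $W$ as coordinate vectors otherwise.
  Each split runs 10 restarts of k-means++-seeded Lloyd iterations
  and keeps the best inertia; restart seeds derive from the master
  seed, so the view is reproducible. A degenerate split (identical
  points, or an empty side) falls back to a balanced index split.
* **Centroid linkage** (agglomerative, geometric): merge the pair of
  clusters with the closest centroids (unweighted means of member
  coordinates), same coordinate convention.

Row-embedding (using rows of $W$ as coordinates) was chosen over a
classical-MDS embedding for the geometric views when no features
exist: it is deterministic, parameter-free and avoids an extra
eigendecomposition with its sign ambiguities.

Each view dendrogram is mapped back to a similarity matrix by
$$S'_{ij} = \frac{N - |T_{ij}|}{N-2} \in [0,1],$$
which assigns 1 to sibling leaves and 0 to pairs first joined at the
root.

## The blending model

$$S_{\mathrm{blend}} = c_0 W + \sum_{i=1}^{k} c_i\,
\bigl(W^{p_w} \odot S_i^{p_{s_i}}\bigr)$$

with element-wise powers and products, simplex coefficients
($c_i \ge 0$, $\sum c_i = 1$) and exponents bounded to $[0, 4]$ — a
permissive range that allows strong sharpening (exponents $> 1$ make
high similarities more distinct) and softening (exponents $< 1$). All
quantities are unitless. Conventions and their reasons:

* $0^0 := 1$ (R's native convention), so $p_w = 0$ cleanly deletes
  the $W$-gating and the configuration $c_1 = 1, p_w = 0$ reproduces
  a pure view exactly.
* Unconstrained optimizer proposals are projected onto the feasible
  set by clip-at-zero plus renormalization (uniform fallback for an
  all-zero vector) and exponent clipping. Clip-and-renormalize was
  preferred over a softmax because it preserves exact zeros, and
  learned configurations do switch views off entirely.
* $W$ is blended as loaded, without pre-normalization to $[0,1]$;
  exponents interact with scale, so users supplying matrices far from
  $[0, 1]$ should be aware the $W$-gate is on that scale. The view
  matrices are always in $[0,1]$ by construction.
* The identity configuration ($c_0 = 1$) makes the whole pipeline
  reproduce plain average linkage on $W$ bit-exactly, and is seeded
  into every search as the baseline.

## Fitness and the surrogate-assisted search

A candidate parameter vector is scored by the Dasgupta cost of
average linkage applied to its blended matrix. The **optimal**
variant measures that cost on the full input. The **robust** variant
averages, over $B$ bootstrap subsamples of the items, the cost on the
subsample divided by the plain average-linkage cost on the same
subsample; the identity configuration therefore scores exactly 1,
giving an absolute reference, and the normalization makes resamples
of different effective size comparable. "Bootstrap" is implemented as
sampling $n$ items with replacement and collapsing to the unique
items: duplicated items would create artificial zero-distance twins
inside the linkage. The resample index sets derive from the master
seed and are shared across all candidate evaluations, so candidates
are compared on common ground. Two evaluation levels control expense:
full evaluations use `B_full` resamples (default 10), cheap
hill-climb evaluations use `B_cheap` (default 3).

The search has three phases:

1. **LHS warm-up** (`n_warmup = 64`): Latin-hypercube samples over
   the raw box (coefficients in $[0,1]$ pre-projection, exponents in
   $[0,4]$), plus the identity configuration as sample 0, all fully
   evaluated.
2. **One-time surrogate training**: a random-forest regressor (300
   trees) from projected parameter vectors to fitness. A tree
   ensemble handles the non-smooth, interaction-heavy response
   surface without kernel tuning. The model is trained once on the
   warm-up and reused unchanged; if the warm-up fitness is constant,
   proposals fall back to uniform random injection.
3. **Iterative rounds** (`n_rounds = 10`): each round screens
   `pool_size = 2048` uniform candidates through the surrogate,
   fully evaluates the `n_inject = 4` best-predicted, then refines
   the incumbent with `n_hill = 20` steps of Gaussian perturbation
   (sd 0.1 on coefficients, 0.25 on exponents) accepted only when
   strictly better under the cheap fitness, and re-scores the result
   with the full fitness.

Every stochastic component draws its seed from the master seed
through a counter-based splitter, which makes runs bit-reproducible
and gives a useful nested-budget property: growing `n_rounds` extends
the evaluation sequence without perturbing earlier rounds, so a
larger budget can only improve the best-so-far. Because the identity
configuration is always in the candidate set and selection is by full
fitness, the returned fitness is never worse than the baseline's; in
the optimal variant this means the returned tree's cost never exceeds
the plain average-linkage cost. Default budgets are sized for inputs
up to a few hundred items; all are arguments.

## The beam-search baseline

The baseline keeps a beam of the most promising partial merge
sequences: each state expands its `max_rank` best merges under the
average-linkage criterion, duplicate partitions reached by different
merge orders are collapsed, and the pool is pruned to `beam_width`
states. "Low cumulative linkage cost and a history of high-ranked
merges" describes a priority without pinning down a formula, so
pruning uses a deterministic lexicographic key: the
cumulative merge score $\sum (1 - \bar{s}/\max W)$ over performed
merges (with $\bar{s}$ the merged pair's average similarity),
then the sum of chosen merge ranks, then a canonical partition
fingerprint. After the last round the full Dasgupta cost of every
surviving tree is computed and the cheapest returned. The greedy
merge sequence is retained as a final candidate: a better-scored
prefix can otherwise complete to a worse tree at small widths, and
retaining greedy realizes the intended guarantee that the beam never
ends worse than average linkage. With `beam_width = 1, max_rank = 1`
the search is average linkage bit-for-bit; with widths exceeding the
whole state space it is exact search (verified against the subset-DP
oracle at $n = 5$). The defaults (width 100, rank 5) are the baseline
configuration used throughout the package's experiments.

## Synthetic data

The generators cover five benchmark data topologies —
irregular anisotropic Gaussians, well-separated spherical Gaussians
(centers at least $6\sigma$ apart on a $10\sigma$-spaced grid, so
recovery by average linkage on a Gaussian-kernel similarity is
forced), interleaved half-moons, two-level nested Gaussians with
recorded coarse/fine paths, and discrete binary data with
block-planted bits in which each block contains two exact prototype
copies, guaranteeing tied similarities. Parameters not fixed by the
caller are drawn from documented ranges (cluster counts 3–8,
dimensions 2–16, bit-flip noise 0.05) under the seed. These are
idealized point processes: they contain no count noise, batch
structure, dropout or non-Euclidean geometry, so passing tests on
them demonstrates correctness of the machinery, not performance on
real single-cell data.

The adversarial decoy-clique instance places $\kappa^3$ items on a
$\kappa^2 \times \kappa$ grid: rows are $\kappa$-item decoy cliques
at similarity $s + \varepsilon$, columns are $\kappa^2$-item optimal
cliques at $s$ (defaults $s = 1$, $\varepsilon = 0.1$). Average
linkage provably merges rows first; the column-first reference tree
(balanced within and across columns) defines the optimal possible
improvement. Two useful exact facts: for uniform weights the cost is
topology-invariant ($n(n^2-1)/3$ for unit weights), so any tree that
completes every column before crossing columns attains the reference
cost exactly; and at $\kappa = 2$ the reference matches the exact
subset-DP optimum. At $\kappa = 2$ ($n = 8$) a width-100 beam covers
essentially the whole merge-sequence space and escapes the trap, so
the deception is demonstrated at $\kappa = 3$ ($n = 27$), where the
beam (width 100, rank 5) gains exactly 0%.

The synthetic ontology is a rooted term tree plus a few extra parent
edges (mimicking multi-parent terms), items annotated to leaf terms,
and features whose means follow the hierarchy with
depth-shrinking displacements, so sibling terms are closer than
distant ones. It stands in, at desk scale, for evaluation against a
curated ontology and is labeled synthetic throughout.

## Evaluation metrics

* **Ground-truth cost**: Dasgupta cost against $W_{\mathrm{true}}$
  (1 within a class, 0 otherwise); percent improvement is
  $100\,(c_{\mathrm{base}} - c_{\mathrm{method}})/c_{\mathrm{base}}$,
  positive when the method is cheaper.
* **Robinson–Foulds**: symmetric difference of non-trivial clade
  sets, normalized by the total non-trivial clade count of both trees
  ($2(n-2)$ for two binary trees); 0 for identical topologies, 1 for
  disjoint clade sets.
* **ARI**: permutation-model adjusted Rand index
  (`mclust::adjustedRandIndex` behind the package surface).
* **Community ranking**: each merge of sibling communities $A$, $B$
  is scored by a one-sided Mann–Whitney U test of whether cross
  distances ($1 - S$) stochastically exceed within distances
  (`stats::wilcox.test`: exact for small untied samples, normal
  approximation with tie correction otherwise). Both children inherit
  their merge's p; the root carries none; a merge of two singletons
  is untestable and gets $p = 1$, as does a merge whose distances are
  all identical (the normal approximation is 0/0 there, so the case
  is defined rather than delegated). Ranking is by ascending p,
  larger community first on ties.
* **Ontology-expanded F1**: a term's ground-truth set contains the
  items annotated to it or any descendant. The default direction
  averages, over terms, the best-match F1 against the top-$N$
  communities — this is monotone non-decreasing as communities are
  appended, which the symmetric harmonization is not, and matches
  reading the comparison as "communities against the full set of
  ground-truth types". `direction = "community"` and `"symmetric"`
  are available.
* **Jaccard stability**: mean best-overlap of each reference k-cut
  cluster with the clusters of re-clustered bootstrap subsamples.

## Numerical choices and degenerate inputs

Agglomerative ties (routine on the discrete generator and the decoy
instance) are broken globally toward the pair with the
lexicographically smallest (min leaf index, max leaf index) of
cluster representatives, in the linkage, the beam expansion and the
centroid view alike; the naive textbook re-implementation used as a
test oracle applies the same rule, and merge tables are compared
bit-for-bit. Similarity matrices are validated on load: symmetry to
$10^{-8}$ relative (then exactly symmetrized), non-negative
off-diagonal, no missing values, diagonal forced to zero. Full double
precision is reported everywhere; no rounding is applied to costs.

## Scale of the shipped experiments

The test and acceptance experiments run at deliberately desk-scale
sizes chosen to exercise every code path with exact references
available: decoy instances at $\kappa \in \{2, 3\}$ ($n = 8, 27$),
oracle comparisons at $n \le 8$ (subset DP), planted-view recovery at
$n = 24$ over 10 seeds, generator recovery at $n = 40$, and 500-node
null calibration for the community test. The package itself is sized
for inputs up to a few hundred items with the default budgets; the
spectral view's full eigendecomposition is the asymptotic bottleneck
beyond that.

## Limitations

Only binary, height-free hierarchies are produced; ultrametric or
non-binary structures are out of scope. The robust variant optimizes
a ratio and can, by design, return a tree whose full-data cost is
slightly above the greedy baseline when stability and cost disagree —
the optimal variant never does. The search is derivative-free and
stochastic: it carries no optimality guarantee beyond never ending
worse than its baseline, and its defaults were sized for hundreds of
items, not atlases. Real-data preprocessing (normalization, feature
selection, nearest-neighbor graph construction) is outside the
package: it consumes a ready-made similarity matrix.
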
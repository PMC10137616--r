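---
title: "Node prioritization from centrality profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node prioritization from centrality profiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CentralityCosDist)
```

# The model

CentralityCosDist prioritizes network nodes by *profile similarity to a
seed set* rather than by any single importance score. Each node is
encoded as a vector of centrality measures — its "topological profile" —
and candidates are ranked by the mean cosine similarity between their
profile and the profiles of known seed nodes. The working assumption is
that functionally related nodes occupy structurally similar positions in
the network, even when they are not direct neighbors; this is what
distinguishes the method from propagation approaches (random walk with
restart) and connectivity-significance approaches (iterative
hypergeometric module expansion), both of which are included as
comparators.

## The feature encoding

`computeCentralityMatrix()` encodes every node as a 9-dimensional
vector:

| column | measure |
|---|---|
| `degree` | degree, normalized by \(n - 1\) |
| `betweenness` | shortest-path betweenness, normalized |
| `closeness` | harmonic-free closeness with the Wasserman–Faust component correction |
| `eigenvector` | principal eigenvector of the adjacency matrix, unit Euclidean norm |
| `pagerank` | PageRank, damping 0.85 |
| `personalized_pagerank` | PageRank with restart mass on the seed set |
| `information` | information (current-flow) centrality |
| `eigenvector_dup` | a duplicate of `eigenvector` |
| `clustering_coefficient` | local transitivity, 0 for degree \(\le 1\) |

Two columns deserve comment. `personalized_pagerank` is the only
seed-dependent coordinate, which is why it (and the duplicate) are
excluded from the unsupervised feature-importance analysis.
`eigenvector_dup` exists to honor the method's stated 9-dimensional
encoding, in which eigenvector centrality effectively appears twice; a
duplicated coordinate rescales the cosine geometry but carries no new
information, and `dedupeEigenvector = TRUE` switches to the
8-dimensional variant for users who prefer it.

Definitional choices were pinned against a reference graph-library
implementation: closeness uses the Wasserman–Faust scaling
\((r-1)/\sum d \cdot (r-1)/(n-1)\) on disconnected graphs (\(r\) =
reachable set size), and information centrality is
\(1 / \sum_t R(v, t)\) with \(R\) the effective resistance, computed per
connected component through the regularized Laplacian inverse
\(\Gamma = (L + \mathbf{1}/n_c)^{-1} - \mathbf{1}/n_c\). Eigenvector
centrality is computed by power iteration on \(A + I\) — same
eigenvectors as \(A\), but the shift guarantees convergence on bipartite
graphs — restricted to the largest connected component (other
components score 0, with a warning) with a deterministic tie-break on
the component containing the lexicographically smallest node.

## Ranking

With profiles \(x_v\) and seed set \(S\),
\[
\mathrm{score}(v) = \frac{1}{|S|} \sum_{s \in S}
  \cos(x_v, x_s), \qquad
\cos(u, w) = \frac{u \cdot w}{\lVert u \rVert\, \lVert w \rVert}.
\]
Nodes are sorted by descending score; ties break lexicographically (by
radix order, so results do not depend on the session locale). Raw
centralities are used by default; `zscore = TRUE` standardizes columns
first, which reweights the cosine toward low-variance measures. Nodes
whose profile is the zero vector (possible only for degree-0 nodes in
an 8-dimensional deduplicated encoding) score \(-1\) with a warning.
The default report compiles the top `k = 10` candidates.

Optional *seed pruning* (`pruneSeeds()`) drops seeds whose mean
similarity to the other seeds falls below a threshold \(\tau\); the
default \(\tau\) is the mean off-diagonal seed–seed similarity minus
two standard deviations, so only clear outliers are removed, and the
best-connected seed is always retained.

# Comparator rankers

`rwrRank()` iterates \(p \leftarrow (1-r)\,M p + r\,e\) with \(M\)
column-stochastic and \(e\) uniform on the seeds, to an L1 tolerance of
\(10^{-10}\); dangling-node mass is redirected to the restart vector so
the iterate stays a probability distribution. The default restart
\(r = 0.5\) follows common practice for protein-network propagation.

`diamondRank()` grows the module greedily: each step scores every
outside node by the hypergeometric tail probability of its \(k_s\)
links into the current module given its degree \(k\), module size
\(s_0\), and population \(N\) (all nodes), and admits the lowest-p
node. Ties favor more links into the module, then lexicographic order.
Because mathematically identical p-values can differ in their last bits
depending on how the tail is summed, p-values agreeing to 12
significant digits are treated as tied — without this the expansion
order would depend on floating-point noise rather than on the model.
The ranking's `score` column is the addition priority (monotone with
rank, as for every ranker); the p-value at addition time is reported in
`neg_log10_p`.

# Feature importance

`importanceAnalysis()` asks which centrality measures structure the
node population: nodes are clustered on their (z-scored,
seed-independent) profiles by k-means or DBSCAN, and a random forest is
then trained to predict the cluster labels, with importance measured by
the drop in held-out accuracy when each feature column is shuffled
(10 shuffles, stratified 70/30 split). A constant column yields exactly
zero importance. DBSCAN is implemented in-package (plain frontier
expansion) with an `eps` default chosen by the knee of the sorted
k-nearest-neighbor distance curve; noise points (label \(-1\)) are
excluded from the supervised step. `ternaryCoordinates()` renormalizes
any three non-negative importances to barycentric coordinates for
ternary plotting.

# The synthetic benchmark

`plantedNetwork()` generates a two-block stochastic block model:
within-block edge probability `pIn`, between-block `pOut`, each pair
drawn independently. The first block is the planted "module"; a seeded
fraction of it becomes the seed set and the rest is held out. Node
labels are a seeded random permutation of the id space ("blinded"), so
a degenerate lexicographic comparator has no positional signal to
exploit — without this blinding, any label-ordered baseline would
trivially recover a module that received the alphabetically first
labels. The generator emulates *assortative community structure only*:
it does not produce heavy-tailed degree distributions, overlapping
modules, or weighted edges, so recovery results quantify the method's
behavior under idealized modularity, not on real interactomes.

`plantedRecoveryStudy()` (defaults: 50 replicates, blocks 30/120,
`pIn` 0.25, `pOut` 0.02, a third of the module as seeds) scores a
replicate as a success when the median held-out rank lands in the top
20% of non-seed nodes. `importanceSanityStudy()` builds feature
matrices where one column determines a binary label and checks that
permutation importance singles it out while a constant column scores
exactly zero.

# Numerical choices

- **Exact cosine identities.** Collinearity is detected through
  Cauchy–Schwarz equality (\((u \cdot v)^2 \ge \lVert u\rVert^2
  \lVert v\rVert^2\)), returning exactly \(\pm 1\); for \(v = u\) the
  two sides are computed from the identical product, so self-similarity
  is exactly 1 bit-for-bit.
- **Power-iteration safety factor.** Per-step change below a tolerance
  does not bound the final eigenvector error, so the internal stopping
  tolerance is `tol / 100`, keeping the returned vector within the
  documented `tol` of the true eigenvector on all validation graphs.
- **Locale-independent ordering.** All lexicographic tie-breaks use
  radix sort; `sort()` under a C vs UTF-8 locale can otherwise reorder
  mixed-case identifiers.
- **Hypergeometric tie tolerance.** See the comparator section:
  12 significant digits.

# Validation design

The test suite checks every measure against independent brute-force
oracles (Floyd–Warshall distances, explicit path-counting betweenness,
dense eigendecomposition, dense linear solves for the random walk,
`choose()`-summation hypergeometric tails) on *every* labelled
connected graph with 3–5 nodes — exhaustive enumeration, 1,044 graphs —
plus 100 seeded random connected graphs of up to 20 nodes, at a
tolerance of \(10^{-6}\). Exhaustive enumeration beyond 5 nodes is
computationally infeasible (\(2^{21}\) candidate graphs at \(n = 7\)),
so the random sample extends coverage to larger, denser cases.

# Limitations

- Centralities are computed densely per component; the information
  centrality solve is \(O(n_c^3)\), so networks beyond a few thousand
  nodes per component become slow.
- Cosine similarity on raw centralities lets large-magnitude columns
  (often degree-correlated) dominate; `zscore = TRUE` is the
  alternative, not a fix — standardization changes, rather than
  removes, the implicit weighting.
- The duplicated eigenvector column doubles that measure's weight in
  the cosine by construction.
- The benchmark generator covers assortative planted modules only;
  performance there does not certify performance on scale-free or
  disassortative networks.
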
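---
title: "Geometry and topology of cell states: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and topology of cell states: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctopo)
```

# Overview

`sctopo` characterizes single-cell RNA-seq data through two structural
lenses: the *cell network* (a k-nearest-neighbor graph over cells in a PCA
embedding) and *gene networks* attached to each cell. On the cell network
it computes Ollivier–Ricci curvature and local / relative persistent
homology; on gene networks it computes persistent homology of either an
edge-weighted cell-specific network (CSN) or a node-weighted prior
network. Diagram summaries — total persistence, persistence entropy,
Betti curves — feed three applications: flagging transition cells,
tracking differentiation potential, and augmenting cell-type
classification.

This vignette explains the models, the tunable parameters and their
defaults, what the synthetic fixtures emulate, and the numerical decisions
made where the design was genuinely open. Every empirical claim referenced
here is computed by the test suite (`tests/testthat/`) or by
`scripts/acceptance.R`; the vignette itself states no numbers beyond those.

# Preprocessing and the cell network

Counts are total-count normalized per cell (default target sum `1e4`),
log1p-transformed, reduced to highly variable genes (ranked by variance of
the log-normalized values — the simplest deterministic dispersion
statistic), and embedded with mean-centered PCA. Each principal component's
sign is fixed so its largest-absolute loading is positive, making
embeddings reproducible across platforms. Defaults: 1000 highly variable
genes, 30 components, `k = 15` neighbors, Euclidean metric (cosine and
correlation dissimilarities available). The kNN graph is symmetrized by
union — an edge is kept if either endpoint selects the other — which
preserves sparse bridges between dense regions; ties in distance are broken
by the lower cell index, so the graph is a deterministic function of the
embedding.

# Ollivier–Ricci curvature

Each node `v` carries the measure placing mass `alpha` on itself
(default 0.5) and `(1 - alpha)/deg(v)` on each neighbor. The curvature of
edge `(i, j)` is `1 - W1(m_i, m_j) / d(i, j)`, where `W1` is the exact
Wasserstein distance under shortest-path ground cost and `d` the
shortest-path distance between the endpoints. Node curvature is the sum
over incident edges (mean available as an option for degree-normalized
comparisons).

The transport problem is solved exactly by a successive-shortest-path
solver with node potentials — not entropic regularization — because the
supports are tiny (an edge's supports hold at most `2k + 2` nodes) and
exactness makes the solver directly comparable to an independent
dense-LP oracle, which the tests exercise on random graphs. The ground
metric defaults to hop distance, matching the combinatorial shortest-path
cost in the curvature definition; an edge-length-weighted ground is
available (`ground = "length"`), since the choice is not canonical for
geometric graphs.

Edges in dense, well-mixed regions have positive curvature (endpoint
neighborhoods largely coincide); edges crossing a sparse bottleneck have
low or negative curvature because the two neighborhoods sit far apart in
the graph. One subtlety the test fixtures make explicit: a *densely
populated* one-dimensional filament is not a bottleneck. Its consecutive
neighborhoods overlap more than those of a two-dimensional cloud, so
hop-ground curvature on such a filament is *higher* than in the clusters
it connects. The negative-curvature signature of transition regions
appears when the bridge is locally sparse relative to the neighborhood
size — the regime real PCA embeddings occupy — and the bridge fixture's
defaults (below) are chosen to realize exactly that regime.

# Persistent homology engine

Filtrations are ordered simplex lists; persistence is computed by the
standard boundary-matrix column reduction over the two-element field, with
a compiled kernel and a pivot table. An independent, deliberately naive
left-to-right reduction (`persistence_oracle()`) provides a second code
path; the tests require exact diagram equality between the two on hundreds
of random filtrations. Zero-persistence pairs are dropped everywhere (they
carry no information and destabilize entropy); bars alive in the final
complex keep an infinite death in stored diagrams and are capped only
inside featurization and Wasserstein matching.

Three filtration constructions are provided:

* **Vietoris–Rips** of a point cloud: a simplex enters at its largest
  pairwise distance; the complex is built one dimension above the homology
  dimension of interest (default `max_dim = 1`, so H0 and H1 are exact).
* **Edge-weighted (CSN) filtration**: heavy edges activate first. The
  descending-threshold complex is re-expressed as an ascending filtration
  by the transform `value = delta_max - min(edge weight in simplex)` with
  `delta_max` the largest edge weight. Vertices enter with their heaviest
  incident edge; isolated vertices enter at `delta_max`, so they never
  interact and contribute one full-length component bar. Adding a constant
  to all weights shifts `delta_max` equally and leaves the transformed
  diagram unchanged — a property the tests assert.
* **Vertex-based clique filtration** for node-weighted networks: a vertex
  enters at `delta_max - weight`, an edge at the entry of its
  later (lighter) endpoint, higher simplices at the maximum of their
  faces. Under this rule an H0 bar's length equals the weight prominence
  of a local maximum over its neighborhood, a fact that shapes the
  differentiation-potential analysis below.

Wasserstein distances between diagrams use the L-infinity ground metric on
birth–death points with orthogonal diagonal projection as the
partial-matching slack, solved exactly as an assignment problem through
the same transport solver. Infinite deaths must be capped explicitly
(normally at `delta_max`); the matching order defaults to `q = 1`, a
choice left open by the underlying theory and exposed as a parameter.

# Local and relative persistence of cells

`local_ph()` computes Vietoris–Rips persistence of the point cloud formed
by a cell and its `k_local = 30` nearest neighbors (the center is included
by default; a radius cutoff is available). The filtration runs to the
neighborhood diameter, so H0 total persistence sums all merge scales in the
neighborhood — a direct readout of local sparsity, which is why transition
cells between dense states score high.

`relative_ph()` measures a cell's role in the global structure: the
persistence of the full Vietoris–Rips filtration relative to the
subcomplex spanned by the cell and its `l_size - 1 = 9` nearest neighbors
(the full subcomplex on those vertices at every scale). It is realized by
coning the subcomplex to a virtual apex — a homotopy-equivalent quotient —
and validated in the tests against a direct relative boundary-matrix
reduction. `relative_importance()` is the Wasserstein distance between the
relative and the ordinary diagram, summed over dimensions, with deaths
capped at the filtration scale. The global filtration is truncated at the
90th percentile of pairwise distances to bound complex size; this is
configurable and documented rather than hidden.

Local persistence is computed on ambient Euclidean distances (not
graph-restricted ones) because the Vietoris–Rips construction on the
embedding is the natural continuous companion of the kNN graph.

# Gene networks

**Cell-specific networks.** For cell `k` and genes `x`, `y`, the
association statistic is `rho = n_xy/n - (n_x/n)(n_y/n)`, where each gene's
interval holds the `round(0.1 n)` cells whose expression *rank* is nearest
the cell's own (ties by cell index), and `n_xy` counts cells inside both
intervals. The rank-local window makes the statistic exactly invariant
under strictly monotone transforms of expression, which the tests assert.
Significance (default level 0.01) uses a seeded permutation null —
shuffling one gene's values across cells and recomputing the statistic —
rather than a normal approximation: the permutation null is calibrated by
construction, and the tests verify the realized null retention rate against
its binomial confidence band. One shared permutation per draw serves every
gene being shuffled, which keeps the per-cell cost linear in permutations.
Retained edges are weighted by `rho` and fed to the edge-weighted
filtration. For bivariate-Gaussian dependence the window statistic's
enrichment factor is `1/sqrt(1 - rho^2)`, so edge calls are reliable only
for strong dependence and a few hundred cells — the study sizes used in
the tests respect this.

**Prior networks.** A knowledge-based gene network (read from a TSV edge
list; none is bundled) is attached to each cell by assigning the cell's
log-normalized expression as node weights; network genes missing from the
matrix get weight 0. The vertex-based clique filtration then activates
highly expressed genes first.

**Betti curves** are evaluated on 100 evenly spaced values of a grid
shared across the dataset (spanning `[0, delta_max]` with the dataset-wide
maximum), so per-cell curves are comparable and averageable.

# Downstream analyses

**Transition calling** thresholds a per-cell score at its upper `q`
quantile (default `q = 0.1`; the score is typically local H0 total
persistence, with negated curvature, H1 total and relative importance as
alternatives). The rule is invariant under monotone transforms of the
score. Flagged cells are grouped by connected components of the
flagged-cell-induced subgraph, and each group is associated with the
clusters its members and graph neighbors overlap, ranked by count; a
modified clustering reassigns flagged cells to their transition group.

**Classification** fits a random forest (5000 trees) or an RBF SVM
(cost 0.5), both with class-balanced weights, on gene features, topology
features, or their concatenation, with a stratified split (default 50%).
Metrics are accuracy, *adjusted* balanced accuracy — implemented verbatim
as mean per-class recall minus `1/C`, with the conventional normalization
`(recall - 1/C)/(1 - 1/C)` also reported, since both conventions circulate
— and macro precision/recall, with an empty predicted class contributing 0
to macro precision.

# What the synthetic fixtures emulate

The generators are seeded, pure functions of their parameters, and their
defaults *are* the study conditions of the test suite.

* `make_bridge_clusters()` — two Gaussian state cores (120 cells each)
  joined by 60 bridge cells spread uniformly along the inter-center
  segment with the same noise. Defaults `dim = 12`, `separation = 11`
  (noise SD units): with 12-dimensional noise the cores are balls of
  radius about `sqrt(12)`, so the states are clearly resolved while the
  bridge is a genuinely sparse bottleneck cloud rather than a dense
  filament. This mimics the effective dimensionality of real PCA
  embeddings; in two dimensions the same construction produces a locally
  dense filament whose curvature signature is inverted (see the curvature
  section), which is a property of hop-metric curvature, not an artifact.
  The edge-level claim — bridge edges more negatively curved than
  intra-core edges — is sharpest when the bottleneck is even sparser, and
  the curvature tests exercise it at a wider separation-to-size ratio
  (`separation = 8`, `dim = 15`); at the recovery-oriented defaults the
  node-level aggregate carries the signal, because it includes the
  junction edges.
* `make_ring()` / `make_blob()` — a planted H1 loop and its structureless
  counterpart; with zero noise the loop's birth equals the polygon chord
  and its death `sqrt(3) x radius`, which the tests check exactly.
* `make_modular_network()` — a planted-partition gene network (60 genes,
  4 modules, within/between edge probabilities 0.6 / 0.05), standing in
  for a knowledge-based network while remaining license-free.
* `make_pluripotency_profiles()` — "broad" cells express every module at a
  moderate level; "localized" cells express one module highly and the rest
  near zero. The localized peak defaults to twice the broad level because
  total-count normalization concentrates a module-restricted cell's
  counts into fewer genes; without this concentration the H0 comparison
  between states is dominated by per-network scale and carries no reliable
  direction. Under the clique filtration a broad cell's network connects
  almost immediately (short H0, loops spanning the whole network capped at
  full scale — high H1), while a localized cell's active module stays a
  long-lived isolated component (high H0) whose few internal loops carry
  little H1.
* `make_topo_signal_classes()` — two classes with identical per-gene
  marginals that differ only in dependence structure: 16 genes arranged on
  a latent half-circle (adjacent correlation `cos(pi/16)`, quarter-circle
  pairs exactly independent, anti-correlated ends closing the band) versus
  independent pairs at the same adjacent correlation, plus 48 independent
  noise genes. Per-cell CSNs of the first class form a circular band with
  one loop; of the second, disjoint edges. The noise genes mimic the bulk
  of class-irrelevant genes in real data; they are what makes raw-gene
  interaction hunting hard for a forest while leaving the per-pair CSN
  tests at full power. Without them any dependence difference is also a
  pairwise-visible difference that a large forest exploits directly — a
  fundamental coupling, since network topology is built from pairwise
  statistics.
* `make_count_blob()` — negative-binomial counts with a threefold
  size-factor spread, exercising normalization realistically.

What passing these tests does *not* show: robustness to dropout, batch
effects, doublets, or the highly skewed library sizes of real data —
none of which the fixtures simulate — nor recovery of the biological
results on any published dataset.

# Numerical choices and degenerate inputs

* Homology coefficients: the two-element field (standard for persistence).
* Filtration order: `(value, dimension, vertex tuple)`; any refinement
  placing faces before cofaces yields the same diagram, so the tie-break
  only fixes reproducibility.
* Zero-total-count cells are left as zeros with a warning; constant genes
  yield a zero association statistic with a warning; constant transition
  scores yield no calls with a warning; empty diagrams have entropy 0 by
  convention so feature tables stay total.
* Exact distance ties in the kNN graph and rank ties in CSN windows break
  by the lower cell index.
* The transport solver treats masses below `1e-12` as exhausted; the
  LP oracle drops the one redundant balance constraint, without which a
  dense simplex solver fails on the rank-deficient system.
* Duplicate points are legal: they produce zero-length kNN edges and
  zero-persistence pairs, which are dropped.

# Problem sizes

The suite runs the full transition analysis at 300 cells (the fixture's
default), the differentiation trend at 100 cells over a 60-gene network,
calibration at 150 cells with 1000 permutations, and classification at
400 cells with 64 genes and 200 permutations per null — sizes at which
every planted effect is comfortably detectable while a complete run stays
in the minutes range on one core.

# Known limitations

* Relative persistence recomputes the global filtration per cell, so its
  cost grows quickly with cell number; it is off by default in the
  feature table.
* The CSN permutation null is recomputed per cell; the shared-permutation
  scheme makes this linear in `n_perm` but the constant is still the
  dominant cost of gene-topology feature extraction.
* Hop-ground curvature is purely combinatorial: it cannot distinguish a
  dense filament from a dense blob by length scales, only by neighborhood
  overlap. Use `ground = "length"` when edge lengths matter.
* Only H0 and H1 are computed by default; higher dimensions work but the
  clique/VR complexes grow combinatorially.
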
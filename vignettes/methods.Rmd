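---
title: "Supervised community detection: models, heuristics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised community detection: models, heuristics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commfit)
```

## The problem

Protein complexes — and communities in weighted interaction networks
generally — are groups of nodes that interact more among themselves than with
the rest of the network. The classical way to score a candidate subgraph $C$
is the density fitness

$$f(C) = \delta_{int}(C) - \delta_{ext}(C), \qquad
\delta_{int} = \frac{m_c}{n_c(n_c-1)/2}, \qquad
\delta_{ext} = \frac{\#\text{boundary edges}}{n_c(n - n_c)},$$

with $n_c$ nodes and $m_c$ induced edges in $C$ and $n$ nodes in the network
(`density_fitness()`; $\delta_{ext} = 0$ when $C$ spans the graph). Real
complexes, however, are not uniformly dense: some are cliques, some
hub-and-spoke stars, some linear chains, and many sit in between. commfit
therefore **learns** the community fitness function: known communities are
positive examples, random walks on the network are negatives, each example
is embedded as an 18-dimensional vector of topological features, and a
binary classifier's positive-class probability becomes the score in $[0,1]$
used everywhere downstream. The density fitness is retained (clipped to
$[0,1]$, `density_model()`) as a model-free baseline, and it is the right
scoring function on degenerate inputs such as the disconnected-clique toy
below.

## Data preparation

Known communities are mapped onto the network (members missing from the
network are dropped), and communities with fewer than 3 remaining nodes,
disconnected induced subgraphs, or duplicate node sets are removed
(`clean_communities()`). Highly redundant communities are merged
(`merge_similar()`): in each pass every community merges with its
highest-Jaccard partner when that overlap reaches `j` (default 0.6, the
value used for curated human complex sets), both originals are removed and
the union is appended to the end of the working list, immediately visible to
later comparisons; passes repeat until none merges. The pass structure makes
few merges, which matters when known communities are scarce; ties between
equally overlapping partners break toward the earlier list position so runs
are deterministic, and a 100-pass guard converts pathological inputs into an
error rather than a hang.

The cleaned set is split 70–30 into train and test communities that share
**no induced network edge** (`split_train_test()`): after a random split,
any training community sharing an edge with a test community is transferred
(and vice versa), followed by end-of-list rebalancing toward the target
fraction. Convergence depends on the initial random split; when the
communities cannot be separated in `max_iters` rounds the function says so
and recommends a different seed rather than returning a leaky split.

Negatives are connected random walks (`sample_negatives()`): a random seed
node repeatedly absorbs a uniformly random neighbour of the current
subgraph — uniform, not degree-weighted, which is the simplest reading of
"add a random neighbour" and keeps the sampler unbiased toward hubs. The
number of walks is `scale_factor` (> 1, default 1.1) times the number of
positives, spread evenly over the positive size range; walks that resemble a
positive (Jaccard ≥ 0.5 by default, matching the binary-match evaluation
threshold) are discarded (`filter_negatives()`), which is why slightly more
than one negative per positive is sampled. Negatives are sampled once, from
the full positive size range, and then split 70–30 at random.

## The embedding

`community_embedding()` computes 18 features of the induced weighted
subgraph: node and edge counts, unweighted density, total / mean / max /
variance of edge weights, mean weighted degree, max / median / variance of
degrees, mean / max / variance of local clustering coefficients, degree
assortativity, the leading eigenvalue of the weighted adjacency, the
unweighted diameter, and global transitivity. This set is **this package's
definition** — fixed, ordered, and versioned (`feature_names()`,
embedded in every saved model so stale artifacts are refused). It spans the
axes along which the topologies above differ; a clique maximises the
cohesion features while a star maximises degree concentration with zero
clustering. Degenerate statistics (variance of one value, assortativity of a
regular graph, clustering of degree-1 nodes) are defined as 0 so vectors are
always finite, and only the induced subgraph is consulted, making the
embedding invariant to relabeling and to everything outside the community.
Boundary information is deliberately excluded: the classifier replaces the
$\delta_{ext}$ term of the density fitness.

## Learning the fitness function

`train_fitness()` standardises features and compares three candidate
pipelines — L2-regularised logistic regression, a 500-tree probability
random forest, and depth-3 gradient boosting — by stratified 5-fold
cross-validated **average precision** (area under the PR curve,
`average_precision()`), refitting the winner on all training data. Average
precision is the right selection metric here because the negative class is
deliberately over-sampled and downstream search consumes the score's
*ranking* near the 0.5 decision boundary. Class imbalance is handled with
inverse-frequency weights. An `automl` backend flag exists for delegating
the model search to an external engine; when none is available it falls back
to the grid with a warning. Everything is seeded: fold assignment, the
forest, and boosting all derive from `rng_seed`, and a persisted model
reloads to bit-identical predictions.

Threshold semantics are global: score ≥ 0.5 means "community", and the
search stopping rules below use exactly this convention.

## Candidate search

Every seed (by default one per node of the network, which avoids guessing
the number of communities; maximal cliques, known-community nodes and random
subsets are alternatives) grows independently (`grow_seed()`, parallelised
by `run_search()`):

* The **first step** always adds the neighbour connected by the highest edge
  weight. The model is not consulted: a 2-node subgraph has no topological
  variation for the embedding to work with (the same reason 2-node
  candidates are discarded in post-processing), so the score-based
  termination check begins once the subgraph has three nodes.
* Later steps propose a neighbour per the base heuristic. `greedy_edge_weight`
  takes the neighbour with the highest maximum connecting weight and never
  calls the model per step (a flag controls whether the model still performs
  the termination check). `eps_greedy` picks a uniformly random neighbour
  with probability ε (default 0.01) and otherwise the candidate whose
  addition maximises the model score.
* Two caps keep each step cheap on large networks: above `t1` (default 500)
  boundary neighbours, a uniform sample of `t1` is considered at all; in the
  greedy branch, above `t2` (default 50) candidates, only the `t2` with the
  largest maximum connecting edge weight are evaluated with the model, so a
  step costs at most `t2` model calls plus an `O(t1 log t1)` sort. The
  defaults are chosen so model evaluation, not sorting, dominates.
* Under `eps_greedy_isa`, a proposal that *lowers* the score is accepted
  with probability $e^{(S_{new}-S_{old})/T}$ where $T = T_0\,\alpha^i$,
  with $i = 0$ at the first post-seed step and the temperature updated every
  iteration regardless of acceptance. $\alpha < 1$ cools;
  $\alpha > 1$ is accepted too and heats, which is useful on networks where
  early exploration pays off. `eps_greedy_pseudo_metropolis` replaces the
  exponential with a constant `k_accept` (default 0.1). Both variants also
  stop after `improvement_window` (default 10) iterations without a score
  improvement.
* Growth stops when the boundary is empty, the score would drop below 0.5
  (the offending node is removed first), the window expires, or `max_steps`
  is reached. `max_steps_smart()` sets the budget to the largest known
  community size at or below the Tukey fence $Q_3 + 1.5\,\mathrm{IQR}$
  (linear-interpolation quartiles), so a few giant known communities do not
  inflate every walk.

Ties among equal proposals always break toward the lexicographically
smallest node id, making ε = 0 growth fully deterministic. Each seed's walk
draws from an RNG substream keyed by the global seed and the seed's node
set, so results are identical for any worker count or scheduling order.
Because growth only ever adds boundary neighbours and only ever removes the
last-added node, every returned community is connected, and every returned
community carries a final score ≥ 0.5.

## Post-processing and evaluation

Two-node candidates are dropped (`remove_small()`), then overlapping
candidates are merged (`merge_learned()`) with the same pass structure as
`merge_similar()`, except that the two originals and their union are scored
and only the highest-scoring variant survives — when an original wins, the
other original is discarded. The default overlap measure is the
neighbourhood affinity $|A\cap B|^2/(|A||B|)$ at threshold 0.375 (the
best-performing human-network configuration); Jaccard is available. The
affinity formula and the binary match criterion below are this package's
definitions of measures whose exact published forms live in supplementary
material.

`evaluate_communities()` compares learned against known sets with:

* **Binary matching** (`qi_prf()`): a pair matches at threshold $t$ when
  both node fractions $|C_k \cap C_l|/|C_l|$ and $|C_k \cap C_l|/|C_k|$
  reach $t$ (default 0.5); precision/recall count communities with at least
  one match. Redundant duplicates are invisible to this measure.
* **FMMF** (`fmmf()`): an exact maximum-weight one-to-one matching of the
  known × learned F-similarity matrix; recall $W/|K|$, precision $W/|L|$.
  The one-to-one constraint is what penalises redundancy (duplicating every
  learned community exactly halves precision) and splits (only one fragment
  of a split match is credited). `mmr()` is the recall component.
* **CMFF** (`cmff()`): each community contributes its best F-similarity
  against the other side; partial credit without the matching constraint.
* **Sn/PPV/SPA and the unbiased UnSPA** (`spa_and_unspa()`): the classical
  node-weighted forms overweight large communities (Sn) and ignore learned
  nodes matching no known community (PPV); the unbiased variants average
  per community and normalise by learned size, fixing both.
* **Co-complex edge PR** (`cocomplex_edge_pr()`): pair-level
  precision/recall swept over learned-community scores.

`sensitive_prf()` exposes the pluggable-similarity framework behind CMFF so
any of the overlap measures can be swapped in. The maximum-weight matching
is computed exactly (igraph's bipartite matcher); its optimality is checked
against a brute-force assignment oracle in the test suite.

## Synthetic benchmarks and what passing them shows

`make_clique_toy()` builds disconnected unit-weight cliques — every
connected subgraph of such a graph is itself a clique, so nothing is
learnable there (surviving random-walk negatives are feature-identical to
small positive cliques); the pipeline is validated on it with the density
baseline and must recover the planted cliques *exactly*.
`make_planted_graph()` plants communities of mixed topologies (clique,
star, path, hybrid = path plus chords at probability 0.5) with
intra-community weights from a normal distribution truncated to $(0,1]$
(mean 0.8, sd 0.1) over low-weight background noise (mean 0.1, sd 0.05,
edge probability 0.01 against 100 background nodes) — mimicking the
confidence-score separation of integrated interaction networks while
keeping the classes learnable rather than trivially separable; defaults are
50 communities of 4–10 nodes with a 5% chance of sharing a node with an
earlier community. `make_labeled_fixture()` runs the full preparation chain
on such an instance to produce ready train/test feature matrices.

These generators emulate topology heterogeneity and weight separation; they
do **not** emulate the heavy-tailed degree distributions, correlated noise,
or annotation biases of real interaction data. Passing the planted
benchmark shows the pipeline's machinery is sound, not that a particular
real network will reach any given score.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the toy at 10 cliques
(sizes 3–8), the planted benchmark at its 50-community default, search
determinism checks over 16 random seeds, acceptance-rule calibration at
10,000 Bernoulli trials, matching-oracle comparisons over 200 random pairs
with up to 6 communities per side, and merging postconditions over 1,000
random community sets per operation — sizes at which every property is
checked in seconds while remaining far from trivially small. Duplicate
input edges keep the maximum weight (conservative for confidence scores);
degenerate statistics are 0, never NaN; merging convergence is guarded at
100 passes; and all stochastic components (splits, walks, folds, forests,
ε-draws, acceptance draws) derive from explicit seeds.

## Known limitations

* The 18-feature set is this package's canonical definition; swapping in a
  different list is a versioned configuration change that invalidates saved
  models by design.
* `merge_similar()` merges unconditionally to the union; only
  `merge_learned()` is fitness-aware.
* The non-overlapping-regime guarantee (no two output communities merge into
  a better one) concerns pairs that the overlap measure can see; two
  node-disjoint communities connected by graph edges are never candidates
  for merging.
* Parallelism is single-node (forked workers); per-seed independence is the
  contract that would let a multi-machine layer distribute seeds, but no
  such layer is included.
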
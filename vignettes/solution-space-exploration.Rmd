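---
title: "Exploring the solution space of community-detection algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring the solution space of community-detection algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r}
library(solspace)
```

## The problem

Community-detection algorithms are routinely treated as if they returned
*the* partition of a network. In practice many of them are stochastic —
Louvain, Leiden, Label Propagation and Infomap randomise node visiting
orders or tie-breaks — and many are additionally sensitive to the storage
order of nodes and edges, an artifact of implementation rather than
topology. Two consequences follow: a single run can elevate a minority
partition to apparent representativeness, and runs on a fixed input order
can systematically undersample the set of partitions the algorithm is
actually capable of producing.

`solspace` treats each run as a draw from a *solution space*: the set of
unique partitions an algorithm produces over repeated trials on the same
graph. The package estimates the probability of each unique partition,
decides when enough trials have been run, classifies the overall shape of
the space, and scores individual nodes by how consistently they co-occur
with their neighbours.

## The model

Let $\mathbb{S} = \{P_1, \dots, P_{n_s}\}$ be the unique partitions seen in
$t$ trials, with counts $c = (c_1, \dots, c_{n_s})$. Conditional on the
counts, solution probabilities get a conjugate Dirichlet posterior

$$p \mid c \sim \mathrm{Dirichlet}(\gamma_0 + c_1, \dots, \gamma_0 + c_{n_s}),$$

with $\gamma_0$ a prior count assigned equally to every solution. The
posterior mean for solution $i$ is $(\gamma_0 + c_i)/(n_s\gamma_0 + t)$, and
each marginal is a Beta distribution,
$p_i \mid c \sim \mathrm{Beta}(\gamma_0 + c_i,\; (n_s - 1)\gamma_0 + t - c_i)$,
giving equal-tailed credible intervals $[p_i^\ell, p_i^u]$.

The model is *sequential*: it starts with one dimension (at least one
solution exists) and expands whenever a trial produces a partition not seen
before. Uniqueness is decided by exact set-partition equality
(`canonical_form()`), which is equivalent to the NMI $= 1$ criterion but
immune to floating-point error. Because the posterior depends on the counts
only, the model is exchangeable — the trial order never matters, which is
what justifies permuting the input freshly at each trial.

Exploration stops at the first of:

* **stabilisation** — $\max_i (p_i^u - p_i^\ell) \le \delta$: every
  probability is pinned down to the requested precision;
* **separation** — $\exists\, i^\star: p_{i^\star}^\ell > \max_{j \ne
  i^\star} p_j^u$: one solution is unambiguously dominant;
* **exhaustion** — $t = t_{\max}$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.1 | stabilisation tolerance on credible-interval widths (probability units) |
| `t_max` | 50 | trial budget |
| `gamma0` | 1 | Dirichlet prior count per solution (1 = uniform/Laplace prior) |
| `level` | 0.95 | credible level of the Beta intervals |
| `t_min` | 10 | minimum trials before convergence may be declared |
| `sparse_ratio` | 0.8 | novel-trial fraction at which a space is called Sparse |
| outlier `threshold` | 0.5 | flagging level for agreement scores (always reported, never silently applied) |

Three of these deserve comment.

**`gamma0`.** Only "weakly informative" is required by the model's logic; we
default to $\gamma_0 = 1$, the uniform prior over the simplex, which keeps
every estimate strictly inside $(0, 1)$ and is the least committal choice
that still regularises early trials. It is configurable for users who want
Jeffreys-style ($0.5$) or stronger shrinkage.

**`t_min`.** With a single known solution ($n_s = 1$) the second Beta
parameter vanishes; we take the posterior to be a point mass at 1 with a
zero-width interval. Left unguarded, stabilisation would then fire on the
very first trial. A minimum trial count (default 10) prevents declaring a
Single space before the algorithm has had a fair chance to produce an
alternative; it guards separation identically. The default is deliberately
modest — a deterministic algorithm that has returned the same partition ten
times under ten independent input permutations is unlikely to surprise at
trial eleven.

**`level`.** The credible level is fixed at fit time (0.95 by default)
because the stopping rules are defined in terms of the intervals; changing
the level after the fact would retroactively change what "converged" meant.

## Input-ordering bias and the permutation step

`permute_graph()` produces an *information-preserving permutation*: the node
list is reordered uniformly at random, the edge list is shuffled
independently, and each edge's endpoint order is swapped with probability
1/2. Adjacency, names and weights are untouched, so every order-insensitive
statistic is identical; only the storage order — the thing a correct
algorithm should ignore — changes. The permuted graph is materialised with
physically reordered internal arrays, so the algorithm receives no hint of
the original order.

Comparing an algorithm's output on fixed versus per-run-permuted input is
the operational test for input-ordering bias (`bias_experiment()`): an
order-invariant algorithm gives statistically indistinguishable frequency
tables (chi-square homogeneity test, $\alpha = 0.01$ — the test and level
are our operationalisation of "indistinguishable" and are echoed in the
output), while an order-sensitive deterministic one concentrates all
fixed-order runs on a single partition. Within `explore()` the per-trial
permutation both mitigates this bias and delivers the exchangeability the
model assumes.

## The taxonomy

`classify_space()` assigns one of five labels by a cascade:

1. **Empty** — no valid solution remains. A partition is invalid when all
   nodes share one community, all nodes are singletons, or some community
   induces a disconnected subgraph; a *degenerate* partition (more
   inter-community than intra-community edges) also counts as invalid under
   the default policy, since it contradicts the definition of a community.
   Both checks live in `validate_partition()`; degeneracy is computed
   globally on unweighted edge counts by default (a weighted variant is a
   switch) because the community definition is stated in terms of edge
   counts.
2. **Single** — exactly one valid solution, terminated by stabilisation.
3. **Dominant** — terminated by separation with a valid dominant solution.
4. **Sparse** — novel valid solutions in at least `sparse_ratio` of trials
   ($n_s \approx t$).
5. **Multiple** — otherwise: several recurring solutions with overlapping
   intervals.

Two boundary decisions are worth making explicit. First, reaching $t_{\max}$
does *not* by itself imply Sparse: a budget-exhausted run with a handful of
recurring solutions is Multiple. Second — and less obviously — a Sparse run
need not end at $t_{\max}$: when every trial is novel, the probability mass
spreads over many dimensions, all the Beta marginals concentrate near small
values, and the interval widths can drop below $\delta$ *because* the space
is incoherent. Stabilisation then fires with $n_s \approx t$. For this
reason the Sparse decision is keyed to the novel-solution rate, not to the
termination cause. The Multiple/Sparse boundary is genuinely grey;
`sparse_ratio = 0.8` is our operational cut, reported in the rationale of
every classification so downstream users can re-cut it.

The secondary Multiple condition $\max_i p_i^\ell < 0.5$ is evaluated and
reported in the rationale; when it disagrees with the overlap-based
decision, the classification flags the discrepancy rather than silently
picking one.

`validity_policy = "count_all"` (default) counts invalid partitions in the
model and filters them at classification time — total and valid solution
counts are reported separately. The alternative `drop_invalid` keeps them
out of the model entirely.

## Agreement and outliers

From the solution space and its probabilities, the pairwise agreement matrix

$$\gamma_{uv} = \sum_{i=1}^{n_s} \hat p_i\, \chi_i(u, v), \qquad
  \chi_i(u,v) = \mathbf{1}[u, v \text{ share a community in } P_i]$$

summarises how consistently each node pair is co-classified. A node's
outlier score $\bar\gamma_v^{(+)}$ is the mean of its non-zero off-diagonal
row entries: zero entries mark pairs that never co-occur and are excluded.
Stable nodes score near 1; nodes whose membership shifts across the space
score low. Because "non-zero partners" can mix a node's stable companions
with an occasional visitor, the profile also reports a partner-restricted
mean (over the node's maximal-agreement partners), under which members of a
stable block score exactly 1 relative to each other. Both statistics are
emitted; the flagging threshold (default 0.5) is always reported with the
profile.

## The benchmark generators

`ring_of_cliques(nc, cs, central = TRUE)` builds the canonical test case:
`nc` complete cliques of `cs` nodes joined in a single cycle, plus an
optional hub connected once to every clique. The hub is a designed
structural outlier: by symmetry the graph admits one partition per clique
absorbing the hub (all equally good) plus the partition isolating the hub as
a singleton — so an unbiased algorithm should spread over the symmetric
solutions, and the hub's agreement with any clique node should approach
$1/nc$. Generator conventions, fixed once:

* for `nc = 2` a cycle would duplicate the connecting edge, so the two
  cliques are joined by exactly one edge;
* the hub attaches to the lowest-index member of each clique — the paperless
  choice among symmetric alternatives; any consistent rule preserves the
  symmetric solution structure;
* node names (`c3_n2`, `centre`) are stable and human-readable so agreement
  profiles can be read directly;
* generated edges carry weight 1; all downstream operations accept weighted
  graphs.

`erdos_renyi_graph()` supplies the null model on which community detection
tends to produce Sparse spaces. `rc_reference_partitions()` constructs the
symmetric reference partitions analytically, which lets experiment code
categorise algorithm output exactly instead of heuristically.

What the generators deliberately do *not* emulate: heterogeneous degree
distributions, weighted community structure, overlapping membership, or the
size and density of real collaboration networks. A passing benchmark suite
shows the machinery is correct on graphs whose ground truth is known by
construction; it does not show that any particular algorithm is reliable on
real data — establishing that, per network, is precisely what the package is
for.

## Worked example

```{r}
g <- ring_of_cliques(4, 5, central = TRUE)
fit <- explore(g, "lp", seed = 1)
fit
classify_space(fit)
symmetry_note(fit, k_symmetric = 4)$message
```

```{r, fig.width = 6, fig.height = 4}
plot(fit)
```

The agreement profile localises the instability at the hub:

```{r}
am <- agreement_matrix(fit)
prof <- outlier_profiles(am, threshold = 0.5)
head(prof[order(prof$gamma_bar_plus), ], 3)
```

The bias experiment contrasts a deterministic order-sensitive algorithm
(Walktrap) with an order-invariant one (Label Propagation):

```{r}
bias_experiment("wt", 4, 5, n_runs = 200, seed = 1)
bias_experiment("lp", 4, 5, n_runs = 200, seed = 1)
```

## Numerical and design notes

* **Uniqueness matching** uses the full sorted-block string as a canonical
  token — no hashing, hence no collisions; lookup is a table match.
* **Credible intervals** come from `qbeta()`; the test suite checks them to
  $10^{-8}$ against an independent integrate-and-invert oracle. With both
  stopping predicates true on the same trial, stabilisation is recorded as
  the cause and the dominant index is still reported.
* **Seeding**: `explore()` pre-derives one seed per trial from the master
  seed, so trial $t$ is reproducible in isolation and results do not depend
  on how many trials ultimately run. All seeded entry points restore the
  caller's RNG state.
* **Algorithm adapters** default to the igraph library defaults (resolution,
  walk length, Infomap trials); which partitions an algorithm can reach —
  e.g. whether Leiden isolates the hub — depends on those defaults and the
  library version, so capability claims are characterised per installation
  by `bias_experiment()` rather than hard-coded. Dendrogram-producing
  algorithms (Edge Betweenness, Walktrap) are cut at igraph's default
  optimal-modularity cut; Edge Betweenness gets a configurable node-count
  guard (default 500) because its cost is prohibitive on large graphs.
* **Degenerate inputs**: a single-node graph is a valid graph whose only
  partition is the trivial one; empty files, directed GraphML, non-positive
  weights and malformed edge-list rows are rejected with specific errors;
  duplicate undirected edges are collapsed with summed weights and a
  warning.
* **Problem sizes**: the examples and tests run on benchmarks up to
  `ring_of_cliques(4, 5)` (21 nodes) with trial budgets of 15–50 and
  bias-experiment sizes of 200–1000 runs — large enough for the multinomial
  sampling error on a probability of 0.25 to be a few percent, small enough
  to keep every experiment in seconds to a couple of minutes on one core.

## Limitations

* The model assigns no mass to unseen solutions: it is a finite Dirichlet
  over the solutions observed so far, expanded on discovery — not a
  Dirichlet-process prior. Probability estimates for a Sparse space are
  therefore descriptive, not predictive.
* Consensus construction across a Multiple/Sparse space, overlapping
  communities, and automatic graph-symmetry detection are out of scope;
  `symmetry_note()` requires the user to supply the symmetry count.
* Total runtime scales linearly with trials times the algorithm's own cost,
  which is the practical ceiling on large networks.
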
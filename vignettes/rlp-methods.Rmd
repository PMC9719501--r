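---
title: "Reverse link prediction for epidemic mitigation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse link prediction for epidemic mitigation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlpnet)
```

## The problem

Epidemics travel over contact and transport networks -- proximity contacts,
commuter roads, flight routes. Removing or controlling well-chosen edges
slows the spread, but closing connections has costs, and a mitigation plan
that fragments the network (stranding towns, cutting all routes to an
airport) is usually unacceptable. The question this package addresses is
*preventive* and model-free: using the network structure alone, before any
outbreak, which existing edges should be controlled first, and how many can
be controlled before the network falls apart?

**Reverse link prediction (RLP)** turns the classic link-prediction
machinery around. Forward link prediction scores *absent* node pairs to
guess which edges will appear; RLP applies the same neighborhood-similarity
scores to the *existing* edges. A high score marks an edge as redundant --
its endpoints are already well connected through mutual neighborhoods -- so
it is the edge whose removal costs least connectivity while pruning the
most transmission routes.

## Score functions

For an existing edge $(x, y)$, with $\Gamma(x)$ the neighbor set of $x$
*in the current graph* (so $y \in \Gamma(x)$ and vice versa -- the edge is
scored as it stands, without temporary removal):

| method | score |
|--------|-------|
| CN | $|\Gamma(x) \cap \Gamma(y)|$ |
| JC | $|\Gamma(x) \cap \Gamma(y)| \,/\, |\Gamma(x) \cup \Gamma(y)|$ |
| PA | $|\Gamma(x)| \cdot |\Gamma(y)|$ |
| RA | $\sum_{s \in \Gamma(x) \cap \Gamma(y)} 1/|\Gamma(s)|$ |
| AA | $\sum_{s \in \Gamma(x) \cap \Gamma(y)} 1/\log_2 |\Gamma(s)|$ |

Two conventions matter and are fixed deliberately. First, the neighbor
sets include the opposite endpoint; deleting the edge before scoring would
change PA and JC, and the scored object is the edge in the intact graph.
Second, AA uses the base-2 logarithm exactly as the score is defined here;
many implementations use the natural log, which only rescales AA but
matters for cross-implementation comparability. Any common neighbor of an
edge's endpoints has degree at least 2, so the AA and RA sums are always
finite. These identities and bounds (CN $\le \min \deg - 1$,
$0 \le$ JC $< 1$, PA $\ge 1$ on connected graphs) are enforced by
property tests.

The comparison baseline is **edge betweenness centrality**,
$c(e) = \sum_{\{i,j\}} \sigma(i,j \mid e)/\sigma(i,j)$, summed over
unordered distinct pairs and left unnormalized -- only the ranking is
consumed, so any positive constant factor is equivalent; the convention is
fixed for reproducibility. It is computed exactly (all-pairs shortest-path
counting via igraph) and cross-checked in the test suite against an
independent brute-force enumerator of shortest paths built on BFS
predecessor DAGs. A seeded uniform-random baseline is included as
plumbing for null comparisons.

## The greedy removal engine

`iterative_removal()` repeats: score all existing edges on the *current*
graph, take the top-ranked edge (ties broken by the lexicographically
smallest internal id pair, making runs deterministic), and remove it --
unless that edge is a bridge. The loop stops at the removal budget or
when the top-ranked candidate would disconnect the network
(`would_disconnect`). The number of steps an unlimited run achieves is the
method's **disconnectivity threshold**: the later a method disconnects the
network, the more relations it can control while every node pair stays
reachable. A tree has threshold 0, and no method can pass
$m - n + 1$ removals (the spanning-tree bound).

Two deliberate choices here:

* **Rescoring.** Scores are recomputed after every removal; a single
  static ranking is available (`static_ranking = TRUE`) for sensitivity
  analysis only, since rankings drift as degrees fall.
* **Stop-at-bridge.** The default loop halts when the top candidate is a
  bridge rather than skipping to the next non-bridge edge: the procedure
  removes "in descending order, just before disconnection", and skipping
  would silently change the ranking semantics. A `skip_bridges = TRUE`
  mode exists behind a flag; it is never used in the standard workflow.

Bridges are detected per step in $O(n + m)$; at the scales of interest
(thousands of edges) the full loop is dominated by the scoring, which is
done with sparse matrix products.

## Evaluation metrics

**Largest adjacency eigenvalue.** The Perron root $\lambda_m$ of the 0/1
adjacency matrix governs the epidemic threshold: lower $\lambda_m$, slower
spread. It is computed by power iteration on the shifted operator
$A + I$ -- the shift makes the Perron root strictly dominant even on
bipartite graphs, whose spectra are sign-symmetric -- with a Rayleigh
quotient estimate and a 2-norm residual stopping rule (for symmetric
matrices the residual norm bounds the eigenvalue error; default tolerance
$10^{-10}$). Tests check the closed forms $\lambda_m(K_n) = n - 1$,
$\lambda_m(C_n) = 2$, $\lambda_m(K_{1,k}) = \sqrt{k}$, agreement with
dense eigendecomposition, and the bounds
$\max(\bar d, \sqrt{d_{\max}}) \le \lambda_m \le d_{\max}$.

**Walk count.** The path-count criterion sums the entries of the Boolean
adjacency powers $A^\ell$ for $\ell = 2, \dots, 5$ and reports
$\log_{10}$ of the total. Matrix powers count *walks*, not simple paths --
deliberately so: every route of every length can carry infection, walk
counts are monotone under edge deletion, and exact simple-path counting is
#P-hard, which would defeat the point of an easy criterion. The default
configuration (lengths 2-5, base-10 log, ordered walks, closed walks
included) is exactly what summing all entries of $A^\ell$ produces; both
inclusion toggles are exposed because reasonable variants exist. Counts
are accumulated exactly in integer-valued doubles and the computation
aborts beyond $2^{53}$ rather than round silently; at the intended scales
(thousands of nodes, lengths $\le 5$) totals stay far below the limit.
An explicit walk enumerator (every walk materialized) verifies the counts
exactly on small graphs.

**Why not LCC or efficiency curves?** The engine never disconnects the
network, so the largest-connected-component size is constant by
construction; the removal count at disconnection (the threshold) replaces
it. Efficiency considers shortest paths only, while all route lengths
carry infection -- hence the walk count.

## The comparison workflow

`compare_methods()` runs each method to its threshold, then compares all
methods "in equal conditions" at a common removal count `common_k`, the
minimum threshold over methods (typically set by edge betweenness, which
hunts bridges and disconnects quickly). Each method is evaluated on its
*own* first `common_k` removals -- equal budget, not a shared edge set.
If two or more methods' eigenvalues agree within `lambda_tie_tol`
(default $5 \times 10^{-7}$, matching the precision at which published
values are compared), the budget is extended one step at a time until one
method attains a strict unique minimum. No method ever removes past its
own threshold: once exhausted it stays at its last feasible count, and if
every method is exhausted before the tie resolves the report flags
`tie_resolved = FALSE` rather than manufacturing a winner. On a 6-cycle,
for instance, every method's threshold is 1 and any single removal leaves
the same path graph, so the tie is structurally unresolvable and is
reported as such.

## Synthetic study conditions

The generators in `generate_graph()` produce the topology classes that
determine which score function wins, and they define the conditions under
which the package's stochastic claims are tested:

* `scale_free` -- Barabasi-Albert attachment (default `attachment = 3`),
  the hub-dominated regime where PA excels;
* `small_world` -- Watts-Strogatz rewiring (`k = 4`, `p = 0.1`), high
  clustering with short paths, the regime of the CN family;
* `regular_lattice` -- circulant rings, the regime where JC's
  normalization pays off;
* `uniform_random` -- Erdos-Renyi plumbing for property tests.

The headline stochastic check uses 20 seeded scale-free graphs with
$n = 200$ and attachment 3 -- large enough for a clear hub structure,
small enough that the full per-step rescoring loop (including
edge-betweenness recomputation) runs in seconds per graph -- and asserts
that the mean disconnectivity threshold of PA is at least that of EB.
The acceptance script's method comparison uses a single seeded scale-free
graph with $n = 120$ for the same reason. These generators emulate degree
structure only: real contact networks also carry weights, temporal
structure, and community geography that the synthetic families do not,
so passing tests demonstrate correctness of the machinery and the
direction of the structural effect, not quantitative transfer to any
particular empirical network.

## Numerical choices and degenerate inputs

* Input graphs are canonicalized: directions and weights dropped (the
  model is a simple Boolean graph; weighted extension is future work),
  self-loops removed, reciprocal duplicates collapsed. Canonicalization
  is idempotent.
* Disconnected inputs are reduced to the largest component with a
  warning; component-size ties break by smallest minimum original label.
* Labels map to contiguous internal ids in sorted order (numeric when all
  labels parse as numbers); MatrixMarket indices are 1-based on disk.
* Tie-breaks everywhere are lexicographic on internal id pairs; this can
  perturb reproduced eigenvalues in the last printed digit when a
  published run used a different unstated order.
* Budget 0 is a no-op trace; trees yield empty traces; a comparison on a
  tree reports `common_k = 0` with a diagnostic rather than an error.
* The random baseline draws from a private seeded stream and restores the
  caller's RNG state, as do the synthetic generators.

## Known limitations

* Greedy removal is not optimal $k$-edge removal (that problem is
  NP-hard); the trace is a priority ordering, not a certified optimum.
* Whether published edge-betweenness runs rescored after each removal is
  not always documented; the default here rescores, and
  `static_ranking = TRUE` lets users check the alternative.
* Weighted, directed, temporal and multilayer networks are out of scope,
  as are infection-state-aware (reactive) variants and simulation-based
  evaluation (SIR/SIS); the method is intentionally structure-only.
* The walk count saturates its exact-integer guard on very dense large
  graphs; at that point the criterion (not the implementation) stops
  being meaningful at length 5 anyway, and the range is configurable.

## A worked run

```{r example, eval = FALSE}
g <- generate_graph(synthetic_spec("scale_free", n = 120, attachment = 3,
                                   seed = 1))
rep <- compare_methods(g, list("pa", "cn", "jc", "aa", "ra", "eb"))
rep
write_report(rep, "report.json")

tr <- iterative_removal(g, "pa", budget = 10, snapshot_metrics = TRUE)
write_trace(tr, "pa-trace.tsv")
```

The same quantities, recomputed from scratch for a seeded graph, are what
`scripts/acceptance.R` writes as JSON.
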
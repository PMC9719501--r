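# rlpnet — reverse link prediction for epidemic mitigation

Epidemics spread over contact and transport networks, and one practical,
model-free way to slow them is to control or remove well-chosen edges —
*without* disconnecting the network, since a mitigation plan that strands
nodes (cuts every route to a city, isolates a ward) is rarely acceptable.

`rlpnet` implements **reverse link prediction (RLP)**: instead of scoring
absent node pairs to predict future edges, it applies the classic
neighborhood-similarity score functions to the *existing* edges of a graph
G(V, E). For an edge (x, y), with Γ(x) the neighbor set of x in the
current graph:

| method | score |
|---|---|
| CN (common neighbors) | \|Γ(x) ∩ Γ(y)\| |
| JC (Jaccard) | \|Γ(x) ∩ Γ(y)\| / \|Γ(x) ∪ Γ(y)\| |
| PA (preferential attachment) | \|Γ(x)\| · \|Γ(y)\| |
| RA (resource allocation) | Σ_{s ∈ Γ(x)∩Γ(y)} 1/\|Γ(s)\| |
| AA (Adamic–Adar) | Σ_{s ∈ Γ(x)∩Γ(y)} 1/log₂\|Γ(s)\| |

A high score marks a *redundant* edge — its endpoints remain well
connected without it — so it can be removed at low connectivity cost while
pruning many transmission routes. The greedy engine repeatedly rescores
the current graph, removes the top-ranked edge, and stops just before the
network would disconnect. Methods are compared against the standard
baseline, edge betweenness centrality
c(e) = Σ_{i,j} σ(i,j|e)/σ(i,j), by three criteria:

* **disconnectivity threshold** — how many ordered removals a method
  sustains before its next choice would split the network (higher is
  better);
* **largest adjacency eigenvalue λ_m** — the Perron root that governs the
  epidemic threshold (lower is better);
* **walk count** — log₁₀ of the total number of routes of lengths 2–5,
  computed exactly from Boolean adjacency-matrix powers (lower is better).

Graphs are plain [igraph](https://r.igraph.org) objects; readers for edge
lists and MatrixMarket files, and seeded scale-free / small-world /
regular-lattice / uniform-random generators, are included.

## Worked example

```r
library(rlpnet)

g <- generate_graph(synthetic_spec("scale_free", n = 120, attachment = 3,
                                   seed = 1))
largest_eigenvalue(g)   # 9.432765
path_count(g)           # 6.793099  (log10 of ~6.2 million routes)

compare_methods(g, list("pa", "cn", "jc", "aa", "ra", "eb"))
#> <eval_report> common_k = 44, extended to k = 44
#>  method threshold k_used   lambda path_count
#>      pa       208     44 6.415472    6.09951
#>      cn        44     44 7.071004    6.26761
#>      jc        46     44 7.538537    6.37985
#>      aa        49     44 6.805657    6.19788
#>      ra        49     44 6.805657    6.19788
#>      eb        59     44 7.049514    6.21124
#> best by lambda: PA; best by path count: PA
```

Reading the report: CN disconnects this scale-free network after 44
removals, so all methods are compared at the common budget k = 44 (each on
its own first 44 removals). Preferential attachment sustains 208 removals
before disconnection — it targets redundant hub–hub edges rather than
bridges — and at the common budget it also achieves the lowest eigenvalue
(6.42 vs 9.43 intact) and the lowest walk count, so it is the best
mitigation ranking for this network by all three criteria.

The removal trace itself is the priority list of edges to control:

```r
iterative_removal(g, "pa", budget = 5)
#> <removal_trace> PA: 5 removal(s), stopped: budget_reached
#>   1. (3, 7) score 600
#>   2. (6, 7) score 552
#>   3. (3, 5) score 506
#>   4. (5, 6) score 462
#>   5. (4, 7) score 460
```

A thin command-line front-end over these functions is installed at
`inst/scripts/rlp.R` (subcommands `score`, `mitigate`, `threshold`,
`evaluate`, `compare`, `reproduce`).

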
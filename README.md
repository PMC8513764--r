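# treeislands

Tree islands and island-aware consensus summaries for sets and multisets
of phylogenetic trees.

## The problem

Phylogenetic analyses routinely return many trees — hundreds of equally
parsimonious trees, or thousands of posterior samples — and the standard
summary is a single consensus tree. But tree distributions are often
structured: they fall apart into *islands*, groups of mutually similar
topologies separated from the rest of tree space. When islands have very
different sizes, the majority-rule consensus is dominated by the largest
island (*large island bias*), and the size disparity itself is frequently a
combinatorial artifact: an island whose trees vary at `i` independent
poorly-resolved regions contains up to `3^i` topologies, because each
NNI-ambiguous edge admits three local resolutions. Island size then
reflects local instability, not support, and the consensus silently
discards the signal carried by smaller islands.

This package is for systematists who want to detect that structure and
summarize each part of it fairly.

## The model

Given a set or multiset of trees 𝒯 on a shared leaf set, a pairwise tree
distance d : 𝒯 × 𝒯 → ℝ₀⁺ and a threshold x ≥ 0, build the graph
G = (V, E) with V = 𝒯 and (T, T′) ∈ E iff d(T, T′) ≤ x. The **islands of
(𝒯, d, x)** are the connected components of G — a mutually exclusive,
exhaustive partition. Each island has a *size* (distinct topologies),
*mass* (total multiplicity) and *density* (size/mass). The built-in metric
is Robinson–Foulds, counted as the un-halved symmetric difference of
nontrivial split sets, so one NNI between binary trees is RF 2 and a 2-RF
island coincides with a 1-NNI island; 1-NNI islands can also be found
directly, without a distance matrix, by generating each tree's NNI
neighborhood, filtering it against the distribution, and merging
overlapping neighborhoods.

Three summaries mitigate large island bias:

* **partitioned-by-island** — one consensus per island, keeping each
  island's resolution visible;
* **weighted-by-island-size** — one majority-rule consensus in which a
  topology with multiplicity `m_t` in an island of size `n_i` gets weight
  `m_t / n_i`, so every island has equal influence (weight totals are
  exactly 1 per island of a set, and can exceed 1 for multisets);
* **rarefied-by-island-size** — draw `n = ⌊s·p⌋` topologies from every
  island without replacement (`s` = smallest island size, `p ∈ [1/s, 1]`),
  take the majority-rule consensus, and repeat over many replicates,
  summarizing the replicate consensuses by strict and majority rule.

Diagnostics connect island size to instability: areas of local instability
in each island consensus (polytomies and sub-100% branches), their
incidence across islands, the `3^i` bound, the average vertex degree of
each island's NNI graph, and Pearson correlations among these quantities.

## Worked example

Plant a three-island distribution (sizes 27, 9, 3 from 3, 2 and 1 unstable
edges on 16 leaves), recover the islands, and run the summaries:

```r
library(treeislands)

planted <- plant_islands(plant_config(n_leaves = 16, i = c(3, 2, 1),
                                      sizes = c(27, 9, 3), seed = 11))
ms   <- planted$trees
dm   <- pairwise_matrix(ms, "rf")
part <- find_islands(dm, ms, x = 2)
part
#> <island_partition> metric 'rf', threshold 2: 3 islands
#>  island size mass density
#>       1   27   27       1
#>       2    9    9       1
#>       3    3    3       1
```

The global majority-rule consensus keeps 10 splits, most contributed by
the biggest island; down-weighting by island size keeps only the 3 splits
that hold up across islands:

```r
majority_rule_consensus(ms)
#> <consensus_tree> majority, 16 leaves, 10 splits displayed
#>   split frequencies: min 69.23%, max 100.00%
w <- island_weights(part, ms)
majority_rule_consensus(ms, weights = w)
#> <consensus_tree> majority, 16 leaves, 3 splits displayed
#>   split frequencies: min 55.56%, max 100.00%
```

Per-island consensus trees expose where each island is unstable, and the
incidence table ties island size to instability:

```r
pc <- partitioned_consensus(part, ms)
st <- island_summary(part)
st$average_degree <- average_degrees(part, dm)
area_incidence(pc, island_stats = st)
#> <incidence_table> areas of local instability x islands
#>            island_1 island_2 island_3
#> I          +        -        -
#> II         +        +        -
#> III        +        -        +
#> IV         -        +        -
#> Total      3        2        1
#> Avg degree 6.00     4.00     2.00
```

The per-island totals recover the planted 3, 2, 1 unstable edges, and the
average NNI-graph degree rises with island size. Rarefaction agrees with
weighting, as it should when both give islands equal influence:

```r
rc <- rarefied_consensus(part, ms, p = 1, replicates = 100, seed = 4)
identical(rc$majority$splits, majority_rule_consensus(ms, weights = w)$splits)
#> [1] TRUE
```

Real tree files enter through `read_trees()` (Newick lists or Nexus TREES
blocks with translate tables; repeated topologies become multiplicities),
and every stage is also available from the shell via the installed
`treeislands` script (`simulate`, `islands`, `profile`, `consensus`,
`weights`, `rarefy`, `instability`, `pipeline`).

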
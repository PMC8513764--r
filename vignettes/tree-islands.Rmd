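---
title: "Tree islands: model, summaries and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree islands: model, summaries and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeislands)
```

## The island model

A collection of inferred trees — equally parsimonious trees, bootstrap
replicates, posterior samples — is treated as a multiset 𝒯 of unrooted
topologies on a shared leaf set: branch lengths, rooting and child order
are discarded for identity, and repeated topologies carry a multiplicity
`m_t`. Given any pairwise distance d and a threshold x ≥ 0, the islands of
(𝒯, d, x) are the connected components of the graph with an edge wherever
d ≤ x. Because connectivity is transitive, islands are always a mutually
exclusive and exhaustive partition (unlike fixed-radius "families", which
can overlap), and they nest: every island at threshold x is contained in
exactly one island at any x′ ≥ x.

The shipped metric is Robinson–Foulds on nontrivial splits, **un-halved**:
`rf(T, T′) = |splits(T) △ splits(T′)|`. On this scale one
nearest-neighbor interchange between binary trees gives RF exactly 2, so
the 2-RF islands are the 1-NNI islands, and integer thresholds 2, 4, 6, …
have a direct rearrangement interpretation. RF is cheap (islands over
thousands of topologies are practical), whereas exact NNI/SPR/TBR
distances are NP-hard in general; `nni_distance_exact()` is therefore a
guarded small-instance breadth-first search (default cap 12 leaves), not a
general-purpose distance. A registry (`register_metric()`) accepts any
user metric, including branch-length-aware ones, without code changes.

`find_1nni_islands()` implements the direct route for binary
distributions: generate each tree's 1-NNI neighborhood (two alternatives
per internal edge, `2(n−3)` neighbors), keep only neighbors present in the
distribution, and merge overlapping neighborhoods until a fixed point.
It provably equals `find_islands()` at RF 2 — a property the test suite
checks on planted sets — but never materializes the distance matrix, which
pays off when unique topologies are many but islands are tiny.

## Why a single consensus can mislead

If a distribution splits into islands of very different sizes, any split
common to the topologies of a dominant island is guaranteed a majority, so
the majority-rule consensus collapses onto the largest island. Size
disparity often has a purely combinatorial origin: an island whose members
differ only at `i` independent NNI-ambiguous edges contains up to `3^i`
topologies (each such edge has three local resolutions). Linear growth in
local instability yields exponential growth in island size, so the biggest
island is typically the *least* internally stable, not the best supported.
The package quantifies this with `bounded_max_size()` (the `3^i` bound),
the average vertex degree of each island's NNI graph (dense graphs mean
rearrangement around few unstable nodes), and `instability_report()`,
which runs four Pearson correlations: island size against instability
totals, size against `3^totals`, totals against average degree, and size
against average degree. Each uses the t transform on n − 2 degrees of
freedom, two-sided, via `stats::cor.test`; a zero-variance input is
reported as an undefined correlation rather than a number.

## The three island-aware summaries

**Partitioned by island.** An independent strict or majority consensus per
island. Splits shared by all members of an island show at 100%; unstable
regions show as polytomies or sub-100% branches.

**Weighted by island size.** Each topology gets weight `m_t / n_i`
(multiplicity over island size). Every island of a set then has total
weight 1; for multisets totals can exceed 1, which is intentional — mass
reflects sampling frequency, while the 1/nᵢ factor neutralizes the
combinatorial size effect. The weighted majority frequency of a split
equals the mean of its within-island frequencies, which is what "equal
island influence" means operationally. `write_trees(..., weights = )`
writes these as literal `[&W m/n]` fractions in Nexus output for
interoperability with programs that honor tree weights.

**Rarefied by island size.** Draw `n = ⌊s·p⌋` topologies per island
without replacement (`s` the smallest island size, `p ∈ [1/s, 1]`,
validated), take a majority-rule consensus, and repeat. `p = 1` minimizes
stochastic information loss from larger islands, which matters when `s` is
small. Replicate `r` draws from a substream derived deterministically from
the user seed (`(seed + 104729·r) mod (2³¹ − 1)`), so the whole analysis
is reproducible and any single replicate can be regenerated in isolation.
Resampled topologies keep their multiplicities, so multiset mass still
weights the per-replicate consensus. With equal island sizes and `p = 1`
the rarefied and weighted summaries provably coincide; the suite asserts
this on planted sets. With unequal sizes they agree only in tendency, and
the package makes no stronger claim.

## Consensus construction and numerical choices

Split frequencies are accumulated in exact integer arithmetic: rational
weights are brought to a common denominator (the lcm of island sizes), so
the majority comparison `2·count > total` is exact and a split at exactly
50% is excluded. Excluding ties guarantees the displayed splits are
pairwise compatible at any cutoff ≥ 0.5; candidates are nevertheless
admitted greedily in decreasing frequency with an explicit compatibility
check, so the same code path would remain safe below the majority
threshold. Displayed splits are reconstructed into a tree by recursive
laminar nesting (splits are stored as the leaf block not containing the
lexicographically first label, so compatible splits form a laminar
family); frequencies are kept as exact ratios and rendered as percentages
with two decimals in node labels, the conventional support-label position,
so output round-trips through standard parsers.

Canonical topology identity uses the same encoding: leaf labels sorted in
the C locale, each nontrivial split serialized as its sorted first-
label-free block, splits sorted, and the key formed from labels plus
splits. Identity is therefore exact, deterministic across platforms, and
independent of input rotation, rooting (a degree-2 root is suppressed) and
branch lengths.

## Areas of local instability

An internal node of a consensus is *unstable* if it is a polytomy or its
subtending split has frequency below 1. Maximal sets of adjacent unstable
nodes form one *area*; adjacency grouping is this package's operational
delineation rule (recorded in the result metadata), chosen because
contiguous ambiguity is best read as one region of conflict. A single
NNI-ambiguous edge or trifurcation admits 3 local resolutions; larger
areas report the product of per-node resolution counts (double-factorial
for polytomies) as an upper bound. Areas are matched across island
consensuses by their focal leaf cluster — the smallest clade containing
the area — with a mutual-overlap rule (≥ half of each, best Jaccard,
one-to-one per island). Both the delineation and the matching are declared
heuristics with tunable parameters; on planted data they are exact, on
real data they should be reviewed by eye like any automated annotation.

## The synthetic generator

`plant_islands()` produces distributions with known structure so every
algorithm can be validated without external data. Base topologies are
separated by seeded random SPR walks from a common random start (walk
length `2 + min_separation`, lengthened on retry); a candidate set of
bases is accepted only when every pair satisfies
`rf ≥ min_separation + 2(i_j + i_k)`, which by the triangle inequality
guarantees members of different islands stay at least `min_separation`
apart — and the generated set is re-verified post hoc via a vectorized
split-incidence computation. Island k is grown as a 1-NNI-connected subset
of the `3^{i_k}` resolution combinations at `i_k` chosen internal edges
(connected growth from the all-zero vector, full enumeration at occupancy
1), so the planted truth partition is exactly the RF-2 partition.

Chosen edges are pairwise non-adjacent *and* not joined by a single edge.
Non-adjacency alone makes the NNI moves commute and the `3^i` count exact;
the extra spacing keeps the collapsed regions of a strict consensus
separated, so the planted island has exactly `i_k` areas of local
instability under the adjacency rule — each planted edge is an independent
instance of instability, which is the mechanism being emulated.

Defaults mirror a realistic parsimony outcome: five islands of sizes 18,
72, 90, 216 and 486 (from i = 4, 6, 6, 8, 9 at the occupancies those sizes
imply) on 76-leaf trees with all multiplicities 1, for 882 topologies in
total; `min_separation` defaults to 4, just above the detection threshold.
The `"geometric"` mass model (multiplicities `1 + rgeom(p = 0.5)`)
emulates posterior-style multisets. What the generator does **not**
emulate: correlated instability (real unstable regions interact),
non-uniform within-island sampling densities, rogue taxa, and
distributions whose islands are not NNI-generated. Passing tests on
planted data therefore validate the algorithms' correctness, not the
biological interpretability of islands in any particular empirical set.

## Problem sizes and determinism

The test suite runs on planted sets of 3–30 topologies with 10–16 leaves
(plus one study-scale default-configuration run of 882 topologies, which
takes about a second), 20 recovery seeds, and 10–100 rarefaction
replicates — sizes chosen so the full suite completes in well under a
minute while still exercising every code path; the rarefaction default of
1000 replicates is kept for analysis use. All stochastic steps take
explicit seeds, restore the session RNG state afterwards, and derive
substreams deterministically, so every reported number is reproducible
from (configuration, seed).

## Known limitations

Exact rearrangement distances beyond the small-instance NNI oracle are out
of scope (use RF thresholds instead); trees must share an identical leaf
set; NNI operations refuse multifurcating trees (the rearrangement is
ambiguous at a polytomy — RF-based islands handle them natively); the
distance matrix is dense, so memory grows quadratically in unique
topologies; and area matching across very dissimilar consensuses is
heuristic by nature.
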
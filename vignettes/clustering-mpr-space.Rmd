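---
title: "Clustering the space of maximum parsimony DTL reconciliations"
author: "dtlclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering the space of maximum parsimony DTL reconciliations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtlclust)
```

## The model

A duplication-transfer-loss (DTL) reconciliation problem is a 6-tuple
$(S, G, \phi, d, t, \ell)$: a rooted binary species tree $S$, a rooted binary
gene tree $G$, a mapping $\phi$ from the gene leaves to the species leaves
(many-to-one and non-surjective mappings are allowed), and non-negative costs
for duplication ($d$), transfer ($t$) and loss ($\ell$).  A reconciliation
mapping $\Phi$ extends $\phi$ to every gene vertex subject to the usual
ancestry constraints: $\Phi(g)$ may not be a proper descendant of a child
image, and at least one child image must lie at or below $\Phi(g)$.  Each
internal gene vertex then induces exactly one speciation (free), duplication
or transfer event, plus zero or more losses along the species edges it skips.
Trees are undated; temporal feasibility of transfers is deliberately not
checked.  A minimum-cost mapping is a maximum parsimony reconciliation (MPR).

Two modelling details worth making explicit:

* **Transfer recipients map directly.** Because losses are only induced when
  the parent's image is ancestral to the child's image, a transferred child
  never incurs recipient-side losses; the recipient vertex in the event tuple
  *is* the child's placement.  The dynamic program therefore uses a separate
  "outside" table (cheapest placement at a vertex incomparable to $s$) with
  no loss term.
* **No losses above the gene root.** The optimum is the minimum placement
  cost of the gene root itself, not of a descent into the tree.

## The reconciliation graph

The number of MPRs can grow exponentially, but the whole space embeds in a
DAG with one *mapping node* per (gene vertex, species vertex) pair that
occurs in some MPR (or that a loss chain passes through) and one *event node*
per induced event tuple.  A *traversal* — pick one event child per mapping
node, keep all mapping children of each chosen event — corresponds one-to-one
to an MPR.  Construction backtracks **every** argmin of the dynamic program,
so co-optimal ties are kept.  Cost comparisons during backtracking use an
absolute tolerance of `1e-9`, which is exact for the integer-valued cost
grids used throughout and safe for reasonable real-valued costs.

With $\ell > 0$ one can show that any mapping node reachable as a transfer
recipient or as a source has equal placement and descend costs and no tied
loss child, so merging the two backtracking contexts into a single node per
$(g, s)$ pair (the published representation) introduces no spurious
traversals.  With $\ell = 0$ tied zero-cost loss chains could conflate loss
placements; the package accepts $\ell = 0$ but the exactness guarantees in
the test suite are stated for positive loss costs, which is also what the
default cost grids use.

## Counting and per-event statistics

All cluster statistics reduce to two passes of completion counting over the
DAG: `below` counts partial traversals beneath a node, `above` counts
completions above it, and the number of traversals through event node $e$ is
$c(e) = \mathrm{above}(e) \prod_{\text{children}} \mathrm{below}$.  From
these:

* **support** of an event is $c(e)/T$ where $T$ is the MPR count of the
  subgraph;
* **mean support** $\sigma$ averages support over the subgraph's
  non-contemporaneous event nodes.  Contemporaneous leaf events occur in
  every MPR of every subgraph (support identically 1), so including them
  would inflate $\sigma$ by a constant; they are excluded by default and can
  be restored with `includeContemporaneous = TRUE`;
* **mean pairwise symmetric distance** $\mu$ uses the per-event
  decomposition: event $e$ lies in exactly one MPR of a pair for exactly
  $c(e)(T - c(e))$ of the $\binom{T}{2}$ unordered pairs, so
  $\mu = \sum_e c(e)(T - c(e)) / \binom{T}{2}$.  This computes the exact mean
  without the much costlier full distance-distribution recursion; the
  package produces distance *histograms* by exhaustive pair enumeration for
  small spaces (at most 200 MPRs) and otherwise from seeded uniform samples;
* the **median** MPR of a subgraph maximizes $\sum_{e \in E(R)} (c(e) - T/2)$
  over traversals $R$, a best-choice DP; this minimizes the summed symmetric
  distance to all MPRs in the subgraph.

Counts are IEEE doubles.  They are exact integers up to $2^{53}$ — far beyond
the $10^{12}$-MPR regimes this method targets — and correctly rounded beyond,
where only ratios of counts enter any decision; a warning is emitted if a
count crosses $2^{53}$.  Supports, $\sigma$ and $\mu$ are derived from these
counts in double precision at the last step.

Ties anywhere (median choices, source selection) are broken by a fixed total
order: mapping nodes sort by (gene preorder index, species preorder index)
and event nodes by (gene, species, type rank S < D < T < L < C, association
keys), so outputs are bit-reproducible.

## Initial clusters from subtraversals

Agglomerative clustering cannot start from singleton MPR clusters when $T$ is
astronomical.  Instead, level-$L$ *subtraversals* are grown from the sources:
level 0 is one subtraversal per source; each round expands every frontier
mapping node by each of its event children (cartesian product), closing
frontier nodes whose only child is a contemporaneous event.  Every MPR has a
unique level-$L$ prefix, so closing each subtraversal into a reconciliation
subgraph (prefix plus everything reachable from its frontier) yields an
initial clustering that exactly partitions MPR space — an invariant the test
suite checks against enumeration at every feasible level.

The implementation searches for the smallest $L$ with at least the requested
number of clusters (default 25).  A level that would exceed the cap (default
200) is refused in strict mode, otherwise the previous level is kept, so the
realized $N$ may differ from the request in either direction.  Level 0 is one
subtraversal per source rather than a single multi-source object, which is
what makes "each MPR represented in exactly one initial cluster" true.

## Linkage criteria and the improvement diagnostics

For a clustering $\mathcal{C} = \{C_1, \dots, C_k\}$ with cluster sizes
$|C_i|$ (MPR counts), mean supports $\sigma_i$ and mean pairwise distances
$\mu_i$:

$$WAS(\mathcal{C}) = \frac{\sum_i |C_i|\,\sigma_i}{\sum_i |C_i|}, \qquad
  WAD(\mathcal{C}) = \frac{\sum_i |C_i|\,\mu_i}{\sum_i |C_i|}.$$

Each agglomeration step evaluates every unordered pair, replacing the pair by
the union of their subgraphs, and performs the merge that most increases WAS
(support criterion) or most decreases WAD (distance criterion), continuing
all the way to $k = 1$ even through worsening merges — the recorded history
lets the user choose $k$ afterwards.  Three deliberate choices:

* Candidate statistics are recomputed on the **union graph**, not combined
  algebraically, because a union of reconciliation subgraphs can contain
  MPRs absent from both parts; $|C_{ij}|$ may exceed $|C_i| + |C_j|$ (after
  the first merge the clusters cover, but need no longer partition, the
  space).
* The linkage compares the **whole-clustering** objective after the
  candidate merge.  Since total weight $\sum_i |C_i|$ itself changes when a
  union gains MPRs, this is not identical to a local pair criterion; the
  global delta is the quantity the improvement score is defined on, so it is
  the one optimized.
* Linkage deltas are compared with an absolute `1e-12` tolerance before the
  deterministic tie-break (earliest-created pair), so floating-point noise
  cannot reorder merges between runs.

Pair statistics are cached and only pairs touching the last merge are
re-evaluated, giving the expected $O(N)$ fresh evaluations per step.  An
optional wall-clock timeout aborts cleanly with a partial history.

The **improvement score** at $k$ is $WAS(\mathcal{C}_k)/WAS(\mathcal{C}_1)$
for support and $WAD(\mathcal{C}_1)/WAD(\mathcal{C}_k)$ for distance
(ratios to the unclustered space; division by zero yields `Inf`, serialized
as `"inf"`).  The **local improvement** at $k$ compares the two clusters
merged between $k$ and $k-1$ against their agglomeration:
$WASlocal_k = WAS(\{C_a, C_b\})/WAS(\{C_{ab}\})$ and
$WADlocal_k = WAD(\{C_{ab}\})/WAD(\{C_a, C_b\})$.  Values well above 1 flag
a $k$ at which splitting is worthwhile.

```{r toy3}
g <- reconcile(dtlFixture("toy3"))
h <- agglomerate(initialClusters(g, minClusters = 2), criterion = "support")
h@perK
improvement(h, 2)
localImprovement(h, 2)
```

## What the synthetic generator emulates — and what it does not

`randomDTLInstance()` draws uniform random binary topologies by recursive
random splits of a shuffled leaf vector, maps gene leaves to species leaves
either uniformly with replacement (allowing the many-to-one, non-onto maps
the model permits) or injectively, and draws costs from a grid whose defaults
are the unit triple plus the two cost settings customary in large-scale DTL
studies, (2, 3, 1) and (1, 4, 1).  This exercises every code path (ties,
transfers, loss chains, degenerate single-leaf trees) but does **not**
simulate gene-family evolution under a generative DTL process: gene trees
are independent of species trees rather than evolved along them, so event
frequencies in these instances are not biologically calibrated.  Passing
tests therefore demonstrate algorithmic correctness (agreement with
brute-force enumeration), not inference accuracy on real gene families.

The brute-force oracle used throughout the tests enumerates all valid
reconciliation mappings of tiny instances (trees of at most 4–6 leaves,
enumeration capped at 500 traversals) and scores them by direct application
of the event definitions — a code path fully independent of the dynamic
program and the counting DP.  Property checks run the two paths against each
other on hundreds of seeded instances; the scale smoke test clusters a
50-leaf-by-50-leaf instance (billions of MPRs) to confirm the polynomial
machinery, not the statistics, at size.

## Degenerate inputs and numerical notes

* Single-leaf trees are supported throughout (the smallest fixture
  reconciles a one-leaf gene tree at cost 0).
* A subgraph with a single MPR has every support 1, $\mu = 0$ and its unique
  traversal as median; a space whose MPRs contain only contemporaneous
  events has $\sigma$ defined as 1.
* Whether $\sigma$ should weight events by their MPR frequency instead of
  averaging over distinct event nodes is not determined by the definitions;
  distinct-node averaging is implemented (the frequency-weighted variant
  corresponds to `includeContemporaneous`-style flags and was not needed).
* All randomness (sampling, the generator, the CLI) flows through R's RNG
  from a single seed; two runs with identical inputs and seed produce
  byte-identical outputs, which the test suite asserts at the file level.

## Limitations

* Only the symmetric distance metric is implemented; path-distance and other
  metrics, dated trees, temporal-feasibility filtering, k-medoids/k-centers
  alternatives, and automatic selection of $k$ (silhouettes, gap statistics)
  are out of scope.
* With $\ell = 0$, tied zero-cost loss chains can conflate loss placements
  in the graph representation (see above).
* The exact pairwise-distance *distribution* is not computed; histograms
  beyond 200 MPRs are sampled estimates.
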
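---
title: "Methods: pharmacokinetics-anchored network pharmacology with netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacokinetics-anchored network pharmacology with netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

Multi-herb formulas act through many constituents on many proteins at
once. A defensible mechanistic hypothesis therefore starts from the
constituents that actually reach the bloodstream (established by a
pharmacokinetic study), collects their putative protein targets from
target-prediction databases, restricts to targets also implicated in the
disease, and then asks the network which of those targets are *hubs*:
central in the bipartite component–target (C–T) graph, dense in its
clustered core, and embedded in a high-confidence protein–protein
interaction (PPI) neighborhood. netpharm implements that chain as plain
R functions over igraph objects and data frames, with a synthetic-data
module that lets the whole pipeline run and be tested without any
database access.

## Consensus targets and the C–T network

Gene symbols arriving from different sources disagree on case and
punctuation; `normalize_symbol()` uppercases and strips hyphens, and all
set operations act on normalized symbols. The consensus set is the plain
intersection of the deduplicated compound-target union with the disease
list. `build_ct_network()` places one undirected edge per asserted
(compound, consensus-target) pair; assertions repeated across source
databases collapse to a single edge, and compounds left with no
consensus target drop out of the graph (on real study data this case has
not been observed; it matters only for sparse synthetic inputs).

## Topological metrics

`node_topology()` follows the NetworkAnalyzer conventions, which differ
from some textbook definitions in two ways that matter for
reproducibility:

* **Per-component computation.** Average shortest path length is the
  mean BFS distance to the other members of the node's *connected
  component*; closeness is its reciprocal (so closeness·avgSPL = 1
  exactly, a tested invariant). Betweenness is normalized by
  `(n−1)(n−2)/2` with `n` the *component* size, not the graph size. The
  bundled fixture certifies both conventions: the middle node of its
  3-protein chain component has betweenness exactly 1, and the 2-protein
  component's members have closeness exactly 1.
* **Simple graphs.** Multi-edges and self-loops are collapsed before
  computation, and shortest paths are unweighted hops; interaction
  confidence scores are never used as distances.

Shortest-path machinery is delegated to igraph; the test suite checks
the assembled metrics against an independent brute-force enumeration of
all shortest paths on small graph classes (paths, cycles, stars,
cliques, bipartite graphs, random graphs up to 8 nodes).

The major-hub rule keeps nodes with degree *strictly greater* than the
mean distinct-neighbor count of the network
(`extract_major_hub_network()`); the computed threshold is always
reported alongside rather than hard-coded, since the mean depends on the
input network.

## MCODE

`mcode()` is a from-scratch implementation of Molecular Complex
Detection in three stages:

1. **Vertex weighting.** For each node, take the subgraph induced by its
   closed neighborhood, find its highest k-core, and set
   `weight = k · density(core)` with `density = 2E/(n(n−1))`. A node
   inside a clique K_m weighs m−1; an isolated node weighs 0.
2. **Cluster prediction.** Seeds are taken in decreasing weight (ties
   broken lexicographically by node id, which makes the output
   independent of vertex input order — a tested property). Expansion is
   breadth-first; a neighbor joins iff it is unassigned and its weight is
   at least `w_seed·(1 − node_score_cutoff)`; a failing node blocks
   traversal through it. Nodes belong to at most one cluster.
3. **Post-processing.** Clusters without a 2-core are discarded;
   "haircut" iteratively shaves members with fewer than two
   connections inside the cluster (the cluster's 2-core); optional
   "fluff" adds boundary neighbors by closed-neighborhood density.
   Scores (density × size) are recomputed after trimming.

Defaults are the published plugin defaults (degree cutoff 2, node score
cutoff 0.2, k-core 2, max depth 100, haircut on, fluff off) — study
reports rarely state these, so they are exposed in `mcode_params()` and
recorded in the pipeline manifest. The k-core primitive is tested
against an exhaustive subset-search oracle on ≤ 10-node graphs, and
cluster prediction against planted-K5 recovery: in 20 independent sparse
backgrounds (30 nodes, edge probability 0.05) the top cluster is exactly
the planted 5-clique in 20 of 20 instances.

## PPI confidence filtering and hub calling

A symbol is a consensus hub iff it passes the topological filter *and*
belongs to the top cluster (`intersect_hubs()`; compound nodes in mixed
cluster memberships simply never match). Scored interaction tables are
filtered at an inclusive cutoff (`score ≥ 0.9` is the conventional
"highest confidence" STRING band) — inclusivity matters at the boundary
and is tested at exactly 0.900. Hub symbols absent from the interaction
table stay in the hub report but not in the graph: transporter hubs
often lack high-confidence interaction partners, yet remain hubs of the
C–T analysis.

## Over-representation analysis

`hypergeometric_p()` uses the exact hypergeometric distribution
(`stats::phyper`); the two-sided p doubles the smaller tail and caps at
1. Tail correctness is tested against explicit `choose()` sums on small
instances, including exact tail complementarity. Design choices, since
ClueGO-style tools document them loosely:

* two-sided by default, one-sided available;
* no multiple-testing correction by default (the conventional workflow
  filters on raw p at α = 0.01 for biological processes and α = 0.05
  for pathways, both inclusive); Benjamini–Hochberg is an opt-in;
* the universe defaults to the union of all GMT members, which is
  reproducible without an external genome annotation, and can be
  overridden — the analysis scripts pass the putative-target union,
  which is the natural background for a target-set query.

## Non-compartmental pharmacokinetics

Profiles carry times in minutes (the sampling unit); all reported
time-based quantities are hours, matching the conventional reporting of
a 40-min peak as Tmax 0.67 h. The estimators:

* **Cmax/Tmax**: maximum observed concentration and the earliest time
  achieving it; an all-zero profile is flagged rather than estimated.
* **AUC0–t**: linear trapezoid by default; log-down trapezoid (exact on
  exponential decline) as an option. The method choice is exposed
  because study reports rarely state it.
* **λ_z and t½**: log-linear least squares over the positive
  concentrations strictly after Tmax, choosing among candidate suffixes
  (≥ 3 points) by maximal adjusted r², ties to the longer run — the
  standard NCA window-selection convention. A fitted slope
  indistinguishable from zero at double precision (≥ −10⁻⁹ per hour) is
  treated as "terminal phase not estimable" rather than reported as an
  astronomical half-life.
* **AUC0–∞** = AUC0–t + C_last/λ_z.
* Zeros before the peak are kept (they shape the absorption phase);
  zeros are excluded from the terminal regression.

On noiseless synthetic profiles the estimators recover the generator's
truth to within 0.01% (t½) and 3.7% (AUC0–∞, limited by the linear
trapezoid on the sparse 360/720/1440-min tail) — inside the 2%/5%
recovery bands the tests assert.

## The synthetic-data generator

`synth_spec()` defines one synthetic study. Its defaults are fixed at
the scale of the motivating study design: 29 compounds, a 1,288-gene
putative-target union, 812 disease candidates, 120 planted consensus
genes. The generator deals every universe gene to some compound (so the
union is exact and every compound has ≥ 1 target), adds Poisson(15)
extra draws per compound, and duplicates 3% of assertions under a second
source tag to exercise deduplication. Disease lists combine the planted
genes with disjoint disease-only symbols, so the downstream consensus
intersection equals the planted count *exactly* — the key bookkeeping
property the pipeline tests lean on.

PK truth defaults: one-compartment oral absorption with ka = 0.08/min,
ke = 0.0023/min (peak near 46 min, terminal half-life near 5 h — the
magnitudes typical of orally absorbed herbal constituents), dose
1.3 g/kg, V/F scaled so peaks land near 180 ng/ml, multiplicative
lognormal noise at 30% CV (mean-preserving), 6 subjects, and the
standard 13-point rat sampling schedule (5–1440 min). Noise is
multiplicative lognormal because concentrations are positive and
bioanalytical error is proportional to level.

What the generator does *not* emulate: correlated target assertions
across chemically similar compounds, scale-free PPI degree
distributions (edges are Erdős–Rényi), hierarchically overlapping
annotation terms, below-quantification-limit censoring, or
between-subject variability in ka/ke. Passing tests therefore
demonstrate algorithmic correctness and planted-structure recovery, not
performance on the statistical quirks of real databases.

## Numerical choices and degenerate inputs

* Ties everywhere break deterministically: lexicographic node ids in
  seeding and ranking, earliest time for tied Cmax, term ids for tied
  p-values.
* Isolated nodes: undefined (NA) average path length, closeness 0,
  betweenness 0, vertex weight 0.
* Empty consensus → empty network with a warning (not an error), so
  sweeps over sparse settings fail softly.
* Duplicate scored PPI pairs with *conflicting* scores are an error;
  exact repeats collapse silently.
* Problem sizes in the routine suites are deliberately small — graphs of
  ≤ 30 nodes for clustering, ≤ 10 for exhaustive oracles, 20 subjects
  for PK recovery, a 1,288-gene universe for the full-scale synthetic
  run — chosen so each suite exercises its planted structure while the
  complete test battery stays quick on a laptop.

## Known limitations

* MCODE here returns disjoint clusters (no overlapping variant) and
  undirected graphs only.
* The hub threshold uses the simple-graph mean degree; tools that
  average neighbor counts on multigraphs can report slightly different
  thresholds on networks with duplicate assertions.
* Enrichment does no ontology propagation or term grouping; a term is
  exactly its GMT member list.
* NCA does no compartmental fitting, dose normalization, or
  bioequivalence statistics.
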
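---
title: "Methods: tissue-restricted cytoskeleton network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-restricted cytoskeleton network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomcyto)
```

# The scientific problem

Glomerular diseases — focal segmental glomerulosclerosis (FSGS), membranous
nephropathy (MN), minimal change disease (MCD), diabetic nephropathy (DN)
and IgA nephropathy — share a final common pathway: dysfunction of the
glomerular filtration barrier, whose mechanical integrity depends on the
actin- and microtubule-based cytoskeleton of podocytes and neighboring
cells. `glomcyto` implements a network pipeline for nominating cytoskeleton
genes likely to matter across these diseases:

1. **Gene-set assembly.** A cytoskeleton annotation universe (union of
   ontology term gene lists) is intersected with a union of
   glomerulus-enrichment datasets (several expression platforms, some with
   mouse identifiers mapped to human orthologs) to define a
   tissue-restricted node universe.
2. **Interactome integration.** Confidence-scored protein–protein
   interactions are combined per edge with a capped noisy-OR and
   thresholded at a combined score of 0.9; curated literature edges carry
   no channel scores and are retained by default. The filtered edges are
   induced on the node universe, keeping isolated genes as disconnected
   nodes.
3. **Topology.** Degree and betweenness centrality
   $C_B(v) = \sum_{\{s,t\},\,v \notin \{s,t\}} \sigma_{st}(v) / \sigma_{st}$
   (unordered pairs, per component) plus component structure: LCC coverage,
   isolated nodes, two-node islets, and the mean interactions per node
   defined as $|E| / |V|$ (half the mean degree — the convention used in
   the field's published summaries).
4. **Cross-disease consistency.** A gene is differentially expressed (DE)
   in a disease when its table reports $p < 0.05$ (raw p-values, no
   multiplicity correction — the upstream selection rule). Genes DE in all
   $K$ diseases with one consistent direction of regulation are the
   candidates; genes DE with both signs are direction-inconsistent and
   excluded regardless of coverage.
5. **Subnetworks.** Candidates are sparsely interconnected, so connected
   views are reconstructed by adding bridge nodes — either all common
   first-order neighbors of at least two seeds, or a greedy Steiner-style
   connector along lexicographically smallest shortest paths. The same
   machinery links candidates to known disease genes.
6. **Prioritization.** Gene–phenotype concordance is the Pearson
   correlation, across phenotypes, between a phenotype-similarity row and
   the gene's closeness profile
   $\Phi(g,p) = \sum_{g' \in \mathrm{genes}(p)} e^{-L(g,g')^2}$, with $L$
   the unweighted shortest-path distance on the *integrated* network.
   Per phenotype, the top-$N$ genes (default 1000) are called predicted.

# Design choices in detail

## Score integration

The combined confidence is $1 - \prod_i (1 - \min(s_i, c))$ with per-source
cap $c = 0.9$. The cap is the load-bearing property: a single evidence
channel can never push an edge past 0.9, so the threshold "combined
$\ge 0.9$" selects edges that either have one maximally-trusted source
(capped exactly at 0.9 — hence the *inclusive* comparison) or independent
support from several channels. An optional prior correction
(subtract-prior, renormalize per channel, recombine, re-add) is off by
default because the prior used by any particular source database release is
not identifiable from the data consumed here.

Curated literature edges carry no channel scores and bypass the threshold
by default; a `strict` mode thresholds them too (and drops score-less
edges). Unordered duplicate pairs are collapsed to the maximum combined
score, and a pair reported curated by any record stays curated.

## Betweenness convention

Pairs $\{s,t\}$ are unordered and each counted once, so a star center with
four leaves scores $\binom{4}{2} = 6$ and every node of a 4-cycle scores
$0.5$. The implementation (Brandes-style accumulation via igraph) is
checked in the test suite against a from-first-principles oracle —
Floyd–Warshall distances plus path counting by adjacency-matrix powers —
exhaustively over all labeled graphs on up to 4 nodes and on random graphs
up to 40 nodes. Exhaustive enumeration of all labeled 8-node graphs
($2^{28}$ graphs) is not informative beyond this, so larger sizes are
covered by seeded random sampling across densities.

## Consistency classifier

A gene absent from a disease table is treated as *not DE* in that disease
(the upstream platform may simply not probe it) rather than as missing
data; this matches consuming published DEG lists as given. Direction is
strictly the sign of the reported fold change; zero fold changes are
rejected at parse time, and duplicate gene rows collapse deterministically
to the minimum p-value. Displayed network percentages use half-up rounding
at one decimal, matching the published table formatting (R's default
banker's rounding would flip some boundary cases).

The permutation null (`consistency_null()`) permutes gene labels within
each disease table independently, preserving each table's DE count and
sign composition while breaking cross-disease coupling — the relevant null
for "how many all-disease direction-consistent genes would arise by
chance".

## Bridging policies

The published procedure introduced "some" common first-order neighbors
without a stated rule, which is not reproducible. Both implemented policies
are deterministic: `common_neighbors` adds *every* background node adjacent
to at least two seeds (a reproducible superset of any manual curation);
`steiner_greedy` produces a compact connector by walking seed pairs in
order of background distance and adding lexicographically smallest shortest
paths only for pairs not yet connected. Subnetwork edges are always the
background-induced edges on the retained nodes; nothing is invented.
Shortest-path reporting uses the same lexicographic tie-break so outputs
are bit-stable across runs and platforms.

## Prioritization variant

The concordance method is specified here as the direct-correlation variant:
closeness kernel $e^{-L^2}$, Pearson correlation over the whole phenotype
profile (the scored phenotype's own column included). Self-distance
$L(g,g) = 0$ makes a phenotype's own known genes score it maximally through
the kernel; disconnected pairs contribute 0; a zero-variance profile
(typically an isolated gene) scores 0 and is flagged rather than dropped,
so ranks remain a complete permutation. Distances are computed on the
integrated network because prioritization should draw on the full
interaction context, not only the tissue-restricted view. Ties in ranking
break lexicographically by gene name.

# The synthetic-data generator

The generator is first-class, tested code: it produces every input the
pipeline consumes, with planted ground truth, so the whole analysis is
exercisable without any downloads.

**What the defaults emulate.** The default configuration reproduces the
statistical shape of the motivating study: a 2030-gene annotation set; nine
enrichment datasets of sizes 148, 102, 310, 165, 914, 130, 202, 675 and
1890 with annotation overlaps 32, 28, 53, 32, 118, 25, 23, 138 and 299
(three datasets issued as mouse identifiers through a complete one-to-one
ortholog map); a constructed annotation-by-enrichment intersection of
exactly 426 genes; and five disease tables planted with 3 consistently
up-regulated, 18 consistently down-regulated and 16 direction-inconsistent
all-disease genes. Enrichment sets draw their non-overlap members from
outside the annotation set, so the intersection is exactly the planted
core — what makes classifier recovery checkable as an equality.

**Interactome.** Three layers: a preferential-attachment background over
the whole universe (heavy-tailed degrees, matching the hub structure of
real interactomes) plus a uniform random-edge fraction; a denser
preferential-attachment layer over 70% of the core with a higher
high-confidence rate, which after thresholding yields a restricted network
with a realistic component profile (roughly 70% of nodes and 99% of edges
in the LCC, a large isolated-node fraction, occasional two-node islets);
and guaranteed high-confidence edges over a configurable fraction of
planted candidate pairs. Per-source scores sit in $[0,1]$; high-confidence
edges carry one channel drawn in $[0.9, 1]$, which caps to 0.9 and
survives the inclusive threshold by construction.

**Disease tables.** DE p-values are uniform below the threshold and non-DE
p-values uniform above it — only the thresholded indicator and the sign
matter downstream, but a log-fold-change magnitude is generated anyway for
realism. Background genes are DE in a truncated-binomial number of
diseases, capped at $K - 1$: the all-disease stratum therefore contains
exactly the planted genes. Diseases are independent in the generator;
real disease cohorts are correlated (shared biology, shared platforms), so
the generated "DE in at least one disease" fraction runs somewhat higher
than published tables at the same per-disease rates. Tests passing on this
generator demonstrate correctness of the pipeline's logic, not calibration
to any real cohort.

**Phenotype data.** Phenotypes are grouped into clusters; each grows a
connected module by randomized breadth-first search inside the background
network's LCC, with cluster members starting from neighboring anchors so
similar phenotypes share neighborhoods. Modules are split by BFS depth
parity — even depths become the phenotype's known genes, odd depths are
held out — which guarantees every held-out gene is adjacent to a known
gene of its own phenotype. The similarity matrix is block-structured
(0.8 within clusters, 0.2 across, unit diagonal). Across 20 seeded
replicates at the default scale, pooled top-decile recovery of held-out
module genes exceeds 80% (checked in the test suite); individual seeds
fluctuate, which is why the property is pooled.

**Determinism.** Every generator stage seeds its own RNG stream derived
from the single configuration seed, so identical configurations give
byte-identical outputs and stages can be regenerated independently.

# Problem sizes and degenerate inputs

Unit tests run the generator at a reduced scale (400-gene universe,
60-gene core, 3 datasets, 4 phenotypes) to keep the suite fast; the
acceptance checks and the reproduction script use the full default scale
(5000-gene universe, 426-gene core, 20 and 10 seeded replicates
respectively). Degenerate inputs are defined rather than erroring where a
convention is defensible: an empty universe yields an empty network; an
edgeless network reports LCC edge fraction 1 (nothing missed); an empty
seed set yields an empty subnetwork. Hard errors are reserved for
contradictions: mixed-species set algebra, planted counts exceeding the
constructed intersection, inconsistency planting with a single disease,
fewer than three phenotypes for correlation scoring, out-of-range
p-values and scores, zero fold changes.

# Known limitations

- Disease tables are generated independently across diseases; cross-disease
  correlation of real cohorts is not modeled.
- The prioritization variant (kernel, whole-profile correlation) is one
  member of the family of closeness-correlation methods; published rankings
  from other variants or other similarity sources will differ.
- Ortholog mapping keeps all targets of one-to-many sources by default
  (`ambiguous = "drop"` is available); tallies are attached so the choice
  is auditable.
- The bridging policies are reproducible supersets/compactions of a
  manually curated published figure, not reconstructions of it.
- Whether published disconnected-node counts include two-node islets is
  ambiguous; the summary reports isolated nodes and two-node islets
  separately rather than guessing.
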
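---
title: "Differential PPI network analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential PPI network analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glionet)
```

## The analysis in one paragraph

glionet compares disease subtypes — its motivating case is glioma: general
glioma, glioblastoma multiforme and low-grade astrocytoma — through the
protein–protein interaction (PPI) neighbourhoods of their over-expressed
genes. Expression tables are reduced to small *seed* gene sets by an
expression cutoff and a Gene Ontology keyword filter; each seed set anchors a
*first-order* PPI network (seeds plus their direct interactors) built from an
interaction database, with confidence-score and taxonomy filters; the
disease-specific networks are compared by graph set algebra (merged
intersection, merged union, and per-disease *unique difference* networks);
overlapping protein complexes are detected by greedy cohesiveness
maximisation; GO over-representation highlights functions specific to each
difference network; and hub lists, isolated nodes and node sets are
reconciled across interaction databases. Because public interaction and
expression resources drift over time, the package treats recovery of
*planted* structure in synthetic data — not any particular historical
database snapshot — as its correctness standard.

## Filtering model

**Expression cutoff.** A gene is kept when its FPKM value under the chosen
condition is at least the cutoff (default 3 FPKM, roughly equivalent to 10
TPM). The boundary is inclusive: what is removed is expression *strictly
below* the cutoff. Missing cells are explicitly missing, never zero, and can
never pass a cutoff — absence of evidence must not create seed genes. The
cutoff is applied to one named condition column; when a table carries
several conditions the caller chooses, since averaging across conditions
would blur exactly the subtype differences the analysis is after.

**Keyword filter.** Gene lists in the thousands are unusable as network
seeds, so genes are restricted to those annotated to at least one GO term
whose *name* contains a keyword (default `"proliferation"`) as a
case-insensitive substring. Matching a word rather than an accession
deliberately sweeps in the whole family of proliferation-related terms.
Only direct annotations are consulted; no propagation along the GO graph is
performed anywhere in the package (see *Enrichment* below).

**DEG tables.** Differential-expression tables are filtered with
`p < 0.05` (strict, the DESeq reporting convention) and
`log2 fold change >= 1` (inclusive), upregulated genes only — the sign of
the fold change matters. All boundaries are arguments.

## First-order network construction

An interaction record survives when (i) its confidence score is at least
`min_score`, if a threshold is given — records without a score fail any
threshold; (ii) *both* interactors carry the filter taxon, if one is given
(the strictest reading of "human nodes only"); and (iii) at least one
endpoint is a seed. The graph contains every surviving endpoint plus every
seed: a seed none of whose interactions survive remains as an isolated
node. This retention rule is essential — genes isolated in *every*
disease-specific network are one of the analysis's headline outputs, and
they would be silently unobservable if seeds were dropped.

Duplicate records collapse to one edge keeping the maximum score (scores
are confidences; the best evidence prevails); self-loops are dropped. The
STRING-style "90% confidence" setting corresponds to `min_score = 0.9`,
i.e. a combined score of 900 on the native 0–1000 scale. The BioGRID-like
dialect carries no scores, so filtering there is taxonomy-only. First-order
(seed + direct interactor) expansion is the construction that turns
sub-hundred seed lists into networks of hundreds-to-thousands of nodes, the
regime the comparative statistics are designed for.

## Graph algebra and statistics

The merged **intersection** keeps nodes present in every network and edges
present (as unordered pairs) in every network — the usual network-merge
semantics; a node-only mode (edges induced from the first input) is also
exposed since either convention is defensible for "merged" networks. The
**difference** network subtracts node-wise: it is the induced subgraph on
the nodes absent from the reference (typically the merged intersection),
because uniqueness of *nodes* is what disease-specific gene discovery needs;
an edge-subtraction mode exists for diagnostics. The **union** takes node
and edge unions with maximum-score conflict resolution.

Per-network statistics are the six standard quantities: nodes, edges, mean
local clustering coefficient, connected components, network diameter and
isolated nodes. Two conventions are worth stating because every network
tool chooses silently:

* nodes of degree < 2 have local clustering 0 and are *included* in the
  mean (a flag excludes them) — this matches common network-analyzer
  behaviour and is what makes sparse seed networks report very low
  coefficients;
* the diameter of a disconnected graph is the largest *finite* shortest
  path, i.e. the maximum component diameter, and 0 for an edgeless graph —
  disconnected networks with isolated nodes must still report a finite
  diameter.

Hubs are the top-k nodes by degree, ties broken by lexicographic gene id:
determinism is documented rather than left to hash order.

## Cohesiveness clustering

Protein complexes are detected by growing candidate node sets that maximise
*cohesiveness*

$$f(V) = \frac{w_{in}}{w_{in} + w_{bound} + p\,|V|},$$

where $w_{in}$ is the total weight of edges inside $V$, $w_{bound}$ the
total weight of edges crossing the boundary, and $p$ a per-member penalty
modelling interactions that were never observed. Confidence scores act as
edge weights where present; unscored edges weigh 1. Growth starts from each
node in decreasing degree order (skipping nodes already covered), evaluates
every single addition of an external neighbour and every single removal of
a member, applies the best strictly-improving move (ties to the smallest
node id) and stops at a local maximum. Candidate pairs with overlap score
$\omega(A,B) = |A \cap B|^2/(|A||B|)$ above a threshold merge by set union,
repeated to a fixpoint — the simplest confluent rule. Surviving candidates
need at least `min_size` members and unweighted density at least
`min_density`. Every node then has exactly one role: **cluster** (one
complex), **overlap** (two or more) or **outlier** (none).

Defaults — penalty 2, minimum size 3, minimum density 0.5, overlap
threshold 0.8 — are the cited method's standard settings; all are
arguments. This is a faithful-in-spirit reimplementation of the
cohesiveness-clustering approach, not a bit-exact clone of any particular
GUI app: where the original leaves order or tie-breaking unspecified we
chose determinism (degree-descending seed order, id-ascending ties), so a
fixed input always yields a byte-identical result.

## Enrichment

Over-representation of a GO term in a study set (typically the nodes of a
difference network) against a background is tested with the upper-tail
hypergeometric probability, one-sided — the analysis looks for enriched
functions, never depletion. The background defaults to every gene occurring
in the relevant interaction database input (plus the seeds); a whole-
annotation-table background is a flag away, since enrichment tools rarely
agree on this choice and it materially changes p-values. Benjamini–Hochberg
correction is applied across all tested terms; raw p-values are also
reported. Only direct annotations are used: with no evidence on whether the
original GUI-based analyses propagated annotations to ancestor terms, the
package defaults to the assumption-free choice and documents it.

## Cross-database consensus

Hub lists and node sets from differently-keyed databases are compared after
mapping into a common identifier space, Ensembl gene ids by default:
symbol-space matching is fragile (symbols are written differently across
databases and typically over-match) and is available only as a diagnostic.
Identifier maps record provenance per row; merging maps coalesces rows that
share any non-missing identifier, field-wise by source precedence, which is
how a partial symbol-sourced map is completed by an Entrez-sourced one.
Unmappable identifiers are always reported, never dropped, and manual
patches — the real-world "thirty ids added by hand" situation — take
precedence over every automated source and are logged. In the merge report,
"unconnected in intersection" counts common nodes with no shared edge in
both inputs, the defensible reading of a merged network's unconnected
nodes; the field is named explicitly so no reader has to guess.

## The synthetic study and what it does (not) show

`generate_synthetic_study()` emits every input the pipeline consumes, with
known planted truth. The default configuration describes a compact
three-subtype study over 600 genes:

| component | default | rationale |
|---|---|---|
| background FPKM | log-normal, meanlog −1, sdlog 1 | heavy-tailed marginal with median ≈ 0.37 FPKM, typical of non-over-expressed genes |
| over-expressed FPKM | log-normal, meanlog 3, sdlog 0.5 | median ≈ 20 FPKM; ≥ 95% of draws clear the 3-FPKM cutoff, so the filter is informative, not saturated |
| shared seeds | 45 (10 hubs, 3 always-isolated, 22 in four complexes of sizes 5/5/6/6, 10 plain) | exercises every downstream consumer of the shared structure |
| unique seeds | 15 per disease, 3 dedicated interactors each | makes difference networks non-trivial and scoreable |
| hub degree | 30, partners from a 150-gene pool | separates hubs cleanly from complex members (degree ≤ 7) |
| noise edges | per-pair probability 2 × 10⁻⁴ (≈ 36 edges) | sparse background interactome; scores mostly below 0.9, 10% above |
| contaminants | 5% of records, non-human taxon, BioGRID dialect only | forces the taxonomy-filter path |
| planted GO term | 90% of unique seeds, 2% of background | clearly enriched but not degenerate |
| id maps | 20% of symbol rows lack an Ensembl id; Entrez map ≈ 98% complete | reproduces the familiar "symbols map badly, Entrez completes them" experience |

Two generator invariants deserve emphasis because the planted truth depends
on them: the always-isolated seeds appear in *no* interaction record of
either dialect, and a disease-unique gene's expression in *other* diseases
is drawn from the background distribution truncated below 3 FPKM, so the
uniqueness labels are exact rather than merely probable. STRING-dialect
scores are written on the native integer 0–1000 scale to force the parser's
rescaling path.

What passing recovery tests on this generator does **not** show: real
interactomes are not unions of cliques, stars and sparse noise; real
expression has correlated, batch-affected marginals; real identifier
ambiguity is adversarial in ways a 20% missingness rate is not; and real
annotation tables have deep DAG structure that direct-annotation enrichment
ignores. The synthetic study validates the machinery — filters, graph
algebra, clustering, testing, consensus — under conditions where the right
answer is known, nothing more.

## Numerical and testing choices

Problem sizes were chosen so the full suite runs comfortably on one CPU:
graph-algebra identities on 500 random triples of up to 150 nodes;
statistics cross-checked against a hand-written BFS/triangle oracle on 100
sparse random graphs; clustering recovery on planted cliques over
k ∈ {2..5}, m ∈ {4..8} noise-free and across 50 noisy replicates; the
hypergeometric tail swept exhaustively against enumeration for all
configurations with N ≤ 12. The null calibration of the enrichment stage
resamples the study set 1000 times against 50 terms of 150 annotated genes
in a background of 1000 — term sizes deliberately large so the discrete
p-value support is fine-grained and the Benjamini–Hochberg family-wise
false-positive rate under the global null can be compared to its nominal
level; with small K the discreteness of the hypergeometric makes the test
conservative and the comparison meaningless. Greedy growth applies moves
only on strict improvement (tolerance 10⁻¹²), which guarantees termination;
cohesiveness of an edgeless set is defined as 0.

## Known limitations

* No GO-DAG propagation, no term–term redundancy reduction, no GSEA-style
  rank tests.
* No live database clients: the package consumes files in the two
  documented dialects and leaves retrieval to the user.
* Interaction semantics are undirected and unsigned; evidence labels are
  filterable strings, not structured ontology terms.
* Only the cohesiveness-based clustering is implemented; other complex-
  detection algorithms are out of scope.
* Historical published node/edge counts from specific 2019 database
  snapshots are not reproduction targets; the package reproduces table
  *shapes* and structural findings (e.g. the existence of seeds isolated in
  every network), which is what remains stable as databases evolve.
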
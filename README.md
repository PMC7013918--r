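# glionet

Differential protein–protein interaction (PPI) network analysis for disease
subtypes, developed around glioma — general glioma, glioblastoma multiforme
and low-grade astrocytoma — but generic over any set of conditions.

Studies of this kind start from per-subtype gene expression, reduce it to
small *seed* gene lists (an FPKM cutoff plus a GO keyword such as
"proliferation"), build a first-order PPI network around each seed list
from an interaction database (BioGRID-like tab files, or STRING-like link
files filtered at combined score ≥ 900), and then ask *what distinguishes
the subtypes*: the merged intersection and union of the networks, each
subtype's **unique difference network** (the induced subgraph on nodes
absent from the merged intersection), topology statistics (nodes, edges,
clustering coefficient, components, diameter, isolated nodes), top-degree
hubs, genes that stay **isolated in every network**, overlapping protein
complexes, and GO terms over-represented in each difference network.

Two pieces of methodology sit at the core:

* **Cohesiveness clustering** — overlapping complexes are grown greedily to
  maximise `f(V) = w_in / (w_in + w_bound + p·|V|)` (internal edge weight
  over internal + boundary weight + a per-member penalty `p`), candidates
  with overlap `ω(A,B) = |A∩B|²/(|A|·|B|) > 0.8` are merged, and complexes
  below size 3 or density 0.5 are discarded; every node ends up a
  `cluster`, `overlap` or `outlier` node.
* **Hypergeometric over-representation** — for a term annotating `K` of `N`
  background genes and `k` of `n` study genes,
  `p = Σ_{i≥k} C(K,i)·C(N−K,n−i)/C(N,n)`, one-sided, with
  Benjamini–Hochberg correction across terms.

Everything is tidyverse-shaped: tabular inputs and outputs are tibbles,
fitted objects have `tidy()`/`glance()` methods, result types have
`autoplot()`s, and networks are igraph objects with documented attributes.
A synthetic-data generator plants complexes, hubs, always-isolated seeds
and an enriched GO term, so the entire pipeline is testable offline against
known truth.

## Worked example

```r
library(glionet)

study <- generate_synthetic_study(generator_config(seed = 1))
res   <- run_pipeline(synthetic_pipeline_config(study))

res$stats$biogrid
#> # A tibble: 5 × 7
#>   Samples             Nodes Edges Clustering Coefficien…¹ `Connected Components`
#> 1 glioma                239   424                  0.0890                     21
#> 2 glioblastoma          240   426                  0.0886                     20
#> 3 astrocytoma           239   424                  0.0890                     21
#> 4 merged intersection   179   378                  0.119                       7
#> 5 merged union          360   518                  0.0591                     48
```

The three disease networks share most of their structure (the merged
intersection holds 179 of ~240 nodes); what is *not* shared is each
subtype's difference network, which is where the disease-specific biology
lives. Three seed genes interact with nothing in any network:

```r
res$consensus$common_isolated
#> [1] "ENSG00000001" "ENSG00000002" "ENSG00000003"
```

Complex detection and enrichment on the glioblastoma side:

```r
glance(res$clusterings$biogrid$glioblastoma)
#> # A tibble: 1 × 8
#>   n_clusters n_nodes n_cluster_nodes n_overlap n_outlier mean_size mean_density
#> 1         23     240              94         0       146      4.09        0.612

tidy(res$enrichments$biogrid$glioblastoma)[1:2, c("accession", "name", "k", "n", "K", "N", "p_value")]
#> # A tibble: 2 × 7
#>   accession  name                           k     n     K     N p_value
#> 1 GO:0099990 synthetic planted process     16    61    55   403 0.00321
#> 2 GO:9900002 synthetic background proce…    6    61    19   403 0.0514
```

The planted enriched term ranks first in the difference network's GO table
(16 of the 61 unique-network nodes carry it, against 55 of 403 background
genes). Scoring the whole run against the planted truth:

```r
score_recovery(study$truth, res)
#> # Recovery against planted truth
#>   isolated_exact min_hub_recovery mean_complex_jaccard mean_difference_purity
#> 1 TRUE                          1                0.979                  0.997
```

All three planted always-isolated seeds are recovered exactly, all ten
planted hubs sit in every network's top ten, detected complexes match the
planted ones at Jaccard 0.98, and 99.7% of difference-network nodes are
planted-unique genes or their exclusive neighbours.

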
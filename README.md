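# hemanet

Analysis of hematopoietic differentiation in parallel miRNA ("force field")
and cytokine ("state") spaces.

Serum-free unilineage cultures drive cord-blood CD34+ stem/progenitor cells
toward the erythroid (E), monocytic (Mo), granulocytic (G) and
megakaryocytic (Mk) fates, sampled at culture days 5, 10 and 15 (stages
T1–T3). Two molecular descriptions of each trajectory are analysed side by
side: miRNA microarray profiles expressed as log2 fold change (logFC)
against the common CD34+ ancestor, and the concentrations of 41 secreted
cytokines on the log2 scale. The package is written for computational
biologists who want to quantify how each space discriminates lineages and
to map the regulatory couplings between the two.

The analysis chain:

* **Displacement spaces** — `compute_logfc()` (miRNA,
  `log2(sample/baseline)`) and `log2_concentration()` (cytokines), with
  explicit missing-value masks and `extreme_features()` for the
  `|logFC| >= 3` labelling.
* **Correlation structure** — pairwise Pearson correlations between sample
  profiles; `within_between_summary()` aggregates them into within-lineage
  and between-lineage means whose ratio measures lineage specificity;
  `two_factor_anova()` (additive model, Type-II SS) tests the
  within/between and miRNA/cytokine factors.
* **Signature selection** — `kmeans_select()` clusters per-lineage logFC
  time courses (Euclidean k-means after a 60% coverage filter) and keeps
  clusters whose centroid reaches a threshold |logFC|; `venn_counts()`
  reports the overlap structure of the four signature sets.
* **Jaccard ordination** — `build_presence_matrix()`,
  `jaccard_distance_matrix()` and `pcoa_embed()` embed the 12
  (lineage, stage) conditions by classical multidimensional scaling of
  Jaccard distances `D = 1 − |A∩B|/|A∪B|` over significant-miRNA supports.
* **SOM mosaics** — `train_som()` and `project_condition()` co-localize
  similarly behaving miRNAs on a grid and repaint it per condition.
* **Bipartite networks** — `build_network()` links selected miRNAs to
  cytokines when their per-lineage series correlate at Pearson
  `r <= −0.9` (negative couplings only, no within-space edges);
  `girvan_newman()` finds communities by iterative removal of
  maximum-betweenness edges with the max-modularity
  (`Q = Σ_s (e_ss − a_s²)`) dendrogram cut; `node_roles()` classifies nodes
  by within-module degree `Z_i = (κ_i − μ_s)/σ_s` and participation
  coefficient `P_i = 1 − Σ_s (K_is/K_i)²`; `descriptors()` reports density,
  diameter and Freeman centralizations.
* **Synthetic data** — `generate_dataset()` draws seeded datasets with
  planted lineage signatures and negatively coupled miRNA–cytokine modules,
  plus `recovery_report()` to score any stage against the ground truth.
* **Orchestration** — `run_pipeline()` runs everything from one (optionally
  YAML/JSON) config and returns a machine-readable report.

## Worked example

```r
library(hemanet)

sim <- generate_dataset(synthetic_config(seed = 1))
mirna_lfc <- compute_logfc(sim$mirna, sim$mirna_reference)
cyt_log2  <- log2_concentration(sim$cytokine)

for (s in list(miRNA = mirna_lfc, cytokine = cyt_log2)) {
  w <- within_between_summary(sample_correlation_matrix(s))
  cat(sprintf("%-8s within %.2f  between %.2f  ratio %.2f\n",
              s$space, w$within_mean, w$between_mean, w$ratio))
}
#> miRNA    within 0.25  between 0.31  ratio 0.81
#> cytokine within 0.62  between 0.46  ratio 1.34
```

The cytokine space is lineage-specific (within/between ratio above 1) while
the miRNA space is not (ratio below 1): the phenotypic "state" separates
lineages, the regulatory "force field" keeps moving. This mirrors the
contrast seen in the real cultures (published ratios 1.09 vs 0.88).

```r
sel <- kmeans_select(mirna_lfc, seed = 11)
sel
#> <signature_selection>
#>   E  : 99 miRNAs (k = 12)
#>   Mo : 70 miRNAs (k = 12)
#>   G  : 70 miRNAs (k = 12)
#>   Mk : 69 miRNAs (k = 12)
venn_counts(sel)[["E&Mo&G&Mk"]]
#> [1] 49
```

About a hundred signature miRNAs for E, seventy for the other lineages, and
roughly fifty shared by all four — the generator plants exactly this
structure and the selection recovers it (recall 0.99 here, via
`recovery_report()`).

```r
g <- build_network(mirna_lfc, cyt_log2, sel$selected$E, "E",
                   cytokine_reference = sim$cytokine_reference)
part <- girvan_newman(g)
part
#> <community_partition> 4 communities, Q = 0.695
central_cytokines(g, part)
#>   module cytokine degree
#> 1      1    CCL15      8
#> 2      2     IL-2     15
#> 3      3     CCL1      8
#> 4      4    ANG-1      7
descriptors(g)[c("density", "diameter", "centr_degree")]
#> $density
#> [1] 0.1042379
#> $diameter
#> [1] 3
#> $centr_degree
#> [1] 0.09561404
```

The erythroid network resolves into communities around its planted
miRNA–cytokine modules (the fourth community collects stray
near-threshold correlations), each anchored by a most-connected cytokine;
`node_roles()` adds the Z–P classification that singles out module hubs and
inter-module connectors.

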
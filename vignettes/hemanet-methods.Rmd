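---
title: "Methods: miRNA and cytokine landscapes of hematopoietic differentiation"
author: "hemanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA and cytokine landscapes of hematopoietic differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemanet)
```

## The scientific setting

Cord-blood CD34+ hematopoietic stem/progenitor cells driven through
serum-free unilineage cultures differentiate into erythroid (E), monocytic
(Mo), granulocytic (G) and megakaryocytic (Mk) precursors. Sampling each
culture at days 5, 10 and 15 (stages T1--T3) yields two parallel molecular
descriptions of the same trajectory:

* the **miRNA space** — microarray intensities of ~1000 miRNA species,
  expressed as log2 fold change (logFC) against the common CD34+ ancestor.
  This space behaves like a *force field*: it reports the transient
  regulatory drive and keeps changing throughout maturation;
* the **cytokine space** — concentrations (pg/mL) of 41 secreted mediators,
  analysed on the log2 scale. This is the *state space*: a comparatively
  stable, lineage-specific phenotypic readout.

`hemanet` implements the complete analysis chain connecting the two spaces:
displacement profiling, correlation-based lineage discrimination,
signature-miRNA selection, Jaccard-distance ordination, self-organizing-map
mosaics, and constrained bipartite miRNA--cytokine network inference with
community detection and node-role classification. Because the original
measurements are not deposited in machine-readable form, the package also
ships a first-class synthetic-data generator with planted ground truth, so
every stage is testable end to end.

## Displacement spaces

`compute_logfc()` forms `log2(sample / baseline)` per miRNA; a positive
value is an upregulation relative to CD34+. Cells with a zero or missing
numerator or denominator are masked, never clamped: the 60% coverage rule
downstream needs explicit missingness. Cytokines are transformed with
`log2_concentration()`; the default pseudocount of 1 pg/mL maps zero
concentrations to 0 and preserves ordering. Whether the published cytokine
barplots show log2 concentrations or ratios against the CD34+ supernatant is
ambiguous in the source; both transforms are provided and log2 concentration
is the default.

## Correlation structure of the two spaces

`sample_correlation_matrix()` computes pairwise Pearson correlations between
sample profiles over the full feature vector (the Euclidean view).
`within_between_summary()` averages the cells of that matrix inside each
lineage block (unordered same-lineage pairs, self-correlations excluded —
diagonal 1s would inflate the means) and across lineage pairs; the overall
within and between values are arithmetic means of the per-group entries and
their quotient is the lineage-specificity ratio of a space. The published
aggregates are exactly reproducible from the printed per-group cells with
`aggregate_lineage_correlations()`:

```{r}
m <- aggregate_lineage_correlations(
  within = c(E = 0.78, Mo = 0.54, G = 0.74, Mk = 0.70),
  between = c(0.66, 0.91, 0.98, 0.56, 0.63, 0.96), digits = 2)
c(m$within_mean, m$between_mean, round(m$ratio, 2))
```

A within/between ratio below 1 (miRNA space) against a ratio above 1
(cytokine space) is the headline contrast: cytokines discriminate lineages,
the miRNome does not, in the plain Euclidean view.

`two_factor_anova()` tests the two factors "within/between lineages" and
"miRNA/cytokine space" on the correlation cells with an additive
(no-interaction) model. The observation set behind the published F-values is
ambiguous (sample-pair correlations versus the 20 aggregated cells), so the
operation is generic; we use Type-II sums of squares because the design is
unbalanced (4 within cells versus 6 between cells per space) and only main
effects are reported. Exact reproduction of the published F-values is not
claimed.

## Signature selection

The upstream study outsourced miRNA selection to the array vendor and states
neither the cluster count nor the significance rule, only that an
unsupervised k-means over time courses with a Euclidean metric was used
after requiring expression values at 60% or more of the time points.
`kmeans_select()` therefore clusters each lineage's (T1, T2, T3) logFC
time courses and calls a cluster significant when its centroid reaches an
absolute logFC of `centroid_tau` somewhere along the course; the signature
is the union of significant clusters.

Two defaults deserve justification:

* `k = 12` (fixed, generous). The selection is a *union over
  significance-gated clusters*, so splitting a cluster never changes the
  union, while merging a small signature cluster into the dominant near-zero
  background silently loses it. On data with one large null cluster, mean
  silhouette width is maximized by `k = 2` — exactly the degenerate merge.
  A silhouette-based `k = "auto"` (range 2..10, smallest k on ties) remains
  available for data without a dominant null mode.
* `centroid_tau = 2` (at least a four-fold displacement somewhere along the
  time course). Signature effect sizes in this system are |logFC| 3--6,
  while background fluctuations stay near or below 1.5; a threshold of 2
  separates the two regimes with margin on both sides.

`venn_counts()` reports the inclusion–exclusion partition of the four
signature sets; the four-way intersection is the "common core" of miRNAs
significant in every lineage.

## Jaccard ordination

The Euclidean view underweights the few strongly displaced miRNAs against
the unchanged bulk. `build_presence_matrix()` therefore switches to a binary
description: rows are the union of selected miRNAs, columns the 12
(lineage, stage) conditions, and an entry is 1 when the miRNA belongs to the
lineage's signature *and* shows |logFC| of at least `stage_tau = 1` at that
stage. The stage gate is our design choice: the source assigns 1 "for each
significant miRNA in each line" without defining stage-level significance,
and an ungated matrix would make a lineage's three columns identical; a
`lineage_only` mode provides that fallback. `jaccard_distance()` compares
condition columns on their supports, and `pcoa_embed()` performs classical
Torgerson scaling (double-centering of `-D^2/2`, eigendecomposition, axes
scaled by the square root of their eigenvalues). Negative eigenvalues —
possible because Jaccard matrices need not be Euclidean — are discarded and
reported; axis signs follow a deterministic first-nonzero-positive
convention. The CD34+ origin has an empty support, where the Jaccard
distance is undefined; `ordinate_conditions(add_origin = TRUE)` places a
flagged origin point at the embedded centroid instead of forcing it into the
distance matrix.

## Self-organizing-map mosaics

`train_som()` is a batch SOM on a rectangular grid (default 10x10, Gaussian
neighborhood, radius decaying linearly from `max(shape)/2` to 0.1 over 100
epochs, seeded random-feature initialisation). Profiles are standardized per
feature before training ("scaled logFC"). The grid geometry and training
schedule used for the published mosaics are unreported; the defaults follow
common SOM practice and are all configurable, so only qualitative properties
(co-localisation of similar profiles, frozen assignments across condition
projections, mass conservation of per-node means) are asserted, not any
specific published mosaic. The terminal radius of 0.1 makes the last updates
effectively per-node batch means, which in practice brings the quantization
error at convergence below its initial value.

## Bipartite miRNA–cytokine networks

`build_network()` imposes the four published constraints: (1) only
miRNA–cytokine pairs, never within-space edges; (2) only significantly
modified miRNAs (the selected set); (3) only negative correlations — the
direct action of a miRNA on a cytokine is inhibitory, positive correlations
arising indirectly; (4) only near-to-unity correlations, Pearson
`r <= -0.9`. Which samples feed the per-lineage correlation is unstated in
the source; we use the lineage's stage series *plus the shared CD34+ origin*
(miRNA logFC 0, cytokine baseline log2 concentration), because three stage
points alone leave |r| >= 0.9 very weakly constrained (under independence, r
over three points is arcsine-distributed and exceeds 0.9 in magnitude about
14% of the time; the anchored four-point series brings the null rate to
5%). Edge weights store r, but all topology metrics are classical
unweighted indices, as in the published descriptors. Isolated nodes are
dropped by default, matching plots that show only connected structure.

`girvan_newman()` removes the highest-edge-betweenness edge, recomputes
betweenness, records the component partition after every removal, and
returns the partition maximizing Newman modularity
`Q = sum_s (e_ss - a_s^2)` over the dendrogram; ties in betweenness break by
lexicographic endpoint order, making runs deterministic. The dendrogram cut
at maximal Q is standard practice; the source does not state its cut rule.
The greedy dendrogram provably need not contain the globally Q-optimal
partition of an arbitrary graph — the suite therefore checks exhaustive
optimality only on separable community structures and cross-checks the
algorithm itself against an independent implementation on random graphs.

`node_roles()` computes the within-module degree
`Z_i = (kappa_i - mu_s) / sigma_s` (population standard deviation;
`sigma_s = 0` gives `Z = 0`) and participation coefficient
`P_i = 1 - sum_s (K_is / K_i)^2` (`K_i = 0` gives `P = 0`). Role quadrants
use the conventional thresholds `Z = 2.5` and `P = 0.62`; the source names
only the quadrants. High-Z nodes organise their module; high-P nodes
connect modules and are the candidate "master nodes" of the landscape.
`descriptors()` reports edge density over all nodes, the diameter of the
largest connected component (published diameters are finite for graphs that
are almost surely disconnected), and Freeman centralization indices for
degree, closeness (largest component) and betweenness.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with full ground truth. Defaults are chosen once to reflect the
study conditions and the published summary statistics, and are not tuned per
seed:

* **Geometry**: 1000 miRNAs, 41 cytokines (the real panel ids), 4 lineages
  x 3 stages, one replicate.
* **Signatures**: 100 miRNAs for E, 70 for the others, 50 common to all
  four; |logFC| at T3 uniform in [3, 6]; 80% of signature displacements
  negative, 80% of cytokine displacements positive (counts enforced, not
  merely expected).
* **Trajectories**: signature miRNAs follow monotone ramps reaching their
  T3 effect through stage fractions (0.2, 0.5, 1) — displacement builds up
  late in differentiation, which also keeps consecutive-stage profiles from
  being near-proportional.
* **Planted modules**: 3 modules of 8 shared miRNAs x 12 cytokines. Module
  stage profiles are an *equiangular orthonormal trio* per lineage:
  mutually uncorrelated over the anchored four-point series and at a fixed
  moderate angle (cos = 1/sqrt(3)) to the monotone ramp direction. This is
  a deliberate departure from all-linear trajectories: with three stages
  plus an anchored baseline, any two monotone ramps correlate near +/-1, so
  planted couplings would be unidentifiable against ramp-vs-ramp
  correlations. Module cytokines trace a negatively sloped copy
  (slope magnitude uniform in [2, 3]) of their module's profile on the log2
  scale; at `noise_sd = 0` and `rho = -1`, every planted pair has Pearson r
  exactly -1 over a lineage's stage series. The narrow slope range keeps
  the three modules' coupled variance balanced, which makes the
  within-lineage cross-stage covariance of the cytokine space positive by
  construction.
* **The miRNA "force field"**: a lineage-shared, stage-specific drift on
  background features (uniform on +/- sd*sqrt(3), default sd 0.85) encodes
  the global maturation programme. Because within-lineage sample pairs
  always span different stages while between-lineage pairs include
  same-stage comparisons, this drift is what produces the published
  within < between asymmetry of the miRNA space. The bounded distribution
  guarantees background features can never cross the significance
  threshold, protecting the selection and the four-way Venn count. A
  lineage's own signature features carry no drift: their dynamics belong to
  the lineage programme.
* **The cytokine "state space"**: analyte baselines spread on the log2
  scale (shared by all samples — the globally positive correlation floor),
  stable lineage-specific secretion offsets on non-coupled analytes, and
  lineage-specific coupled displacements. Both lineage-specific components
  raise within-lineage correlations above between-lineage ones, the
  published ratio > 1.
* **Noise**: iid Gaussian on the log2 scale (default sd 0.1), with one
  pseudo-random stream per table split from the master seed, so adding
  cytokine noise never shifts the miRNA draws.

What the generator does **not** emulate: microarray dye-swap or background
artifacts, Luminex bead-count noise, heteroscedasticity, missing values, or
correlated replicate structure. Passing recovery tests therefore show that
the pipeline is correct and well-calibrated under its own assumptions — not
that it would recover structure from real measurements, whose deposited form
does not permit that comparison.

`recovery_report()` scores inferred signatures (precision/recall per
lineage), inferred edges (per-lineage instances against the planted
couplings when a lineage column is present, unique pairs otherwise), and
community partitions (adjusted Rand index against the planted modules,
restricted to module members).

## Numerical and interface choices

* Missing values are carried as masks (NA) and serialized as the literal
  string `NA`; table output uses 6 significant digits so fixed inputs give
  byte-identical files.
* Sample headers follow the grammar `<lineage>_<stage>[_<replicate>]` with
  closed vocabularies {E, Mo, G, Mk} and {T1, T2, T3}; anything else is a
  parse error.
* Thresholds on |logFC| are inclusive (`>=`), matching the published ">=
  |3|" labelling.
* k-means uses 10 seeded restarts; all stochastic stages take explicit
  seeds, and `run_pipeline()` derives per-stage seeds from one master seed.
* The package's interface is its functions plus `run_pipeline()`, which
  accepts a hierarchical YAML/JSON config surfacing every gap-filling
  default listed above; there is no shell entry point, as the intended use
  is interactive and scripted analysis.
* Problem sizes in the test-suite: the brute-force oracles enumerate
  partitions and shortest paths on graphs of 5--8 nodes; recovery checks
  run the full generator (1000 miRNAs) once and the correlation contrast on
  ten seeds.

## Known limitations

* The exact published network descriptors, modularities and F-values depend
  on unreleased measurements and are treated as plausibility ranges, not
  targets.
* Girvan–Newman returns the max-Q partition of its own dendrogram, which
  for arbitrary graphs can sit below the global modularity optimum; this is
  a property of the algorithm, preserved deliberately.
* The SOM mosaics are qualitative: grid size and training schedules of the
  published figures are unknown.
* Whether per-lineage networks should merge lineage-specific and common
  miRNAs or keep them separate is ambiguous in the source; the merged node
  set is implemented (the selected set already contains both).
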
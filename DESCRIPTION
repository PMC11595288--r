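Package: hemanet
Title: miRNA-Cytokine Landscape Analysis of Hematopoietic Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing unilineage hematopoietic differentiation in
    parallel miRNA ("force field") and cytokine ("state") spaces: log2
    fold-change profiling against a CD34+ ancestor baseline, sample-sample
    Pearson correlation summaries with within/between-lineage contrasts,
    k-means signature-miRNA selection with Venn overlaps, Jaccard-distance
    principal-coordinates ordination, self-organizing-map expression mosaics,
    and constrained bipartite miRNA-cytokine network inference with
    Girvan-Newman community detection, within-module degree / participation
    coefficient node roles and classical graph descriptors. A seeded
    synthetic-data generator with planted signatures and negatively coupled
    miRNA-cytokine modules makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    mclust,
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
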
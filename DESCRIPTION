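Package: momicnet
Title: Multi-Omics Weighted Correlation Network Integration
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of up to three omics layers measured on
    common samples. Builds a weighted correlation network per layer
    (soft-thresholded adjacency, topological overlap, module detection,
    module eigengenes), links layers by directly correlating module
    eigengenes across networks into a trait-anchored multilayer module
    graph, validates module-trait associations with orthogonal partial
    least squares (OPLS) and variable importance in projection (VIP)
    scores, and provides exploratory and integrative ordination (PCA,
    PCoA, pairwise and multiple co-inertia, Procrustes with a permutation
    test). Includes preprocessing for compositional sequencing data
    (prevalence filtering, centered log-ratio transform, outlier
    detection, taxonomic aggregation) and a synthetic multi-omics
    generator with planted modules, shared cross-layer factors and trait
    effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    vegan,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, DimensionReduction, Microbiome,
    Transcriptomics, Proteomics, Software
RoxygenNote: 7.3.3
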
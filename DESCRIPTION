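Package: avalanche
Title: Phylogenetically Weighted Dissimilarity and Unsupervised
    Classification of Forest Inventory Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discriminates woody species assemblages from national forest
    inventory (NFI) plot data.  Builds per-plot mean basal-area community
    matrices from stem records collected on concentric nested subplots,
    derives normalized cophenetic interspecies distances from an
    ultrametric phylogeny, and compares the species-neutral Bray-Curtis
    dissimilarity with the phylogenetically weighted Discriminating
    Avalanche index.  Samples are classified by a divisive isopam-style
    hierarchical clustering (isomap geodesic distances, classical scaling,
    partitioning around medoids) whose splits maximise the number and
    fidelity of indicator species (equalized phi, Fisher's exact test).
    Includes indicator synoptic tables, a full cluster-evaluation suite
    (Mantel test, cophenetic correlation, adjusted Rand index, within
    sum of squares, Kruskal-Wallis on elevation) and a synthetic NFI
    generator for end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    igraph,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
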
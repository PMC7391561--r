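Package: refugeo
Title: Postglacial Colonization Inference and Variation Partitioning for
    Sexual-Apomictic Plant Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct the postglacial colonization history of
    plant populations from dominant-marker (AFLP) and chloroplast sequence
    data, and to quantify the relative roles of ecology, colonization
    history and the occurrence of apomictic conspecifics in shaping the
    geographic distribution of a sexual cytotype. Implements per-population
    genetic indices (haplotype diversity, nucleotide diversity, Nei gene
    diversity for dominant markers, frequency-down-weighted marker rarity),
    Jost's D_est and Mantel isolation-by-distance tests; a grid-based
    colonization-source inference from diversity gradients; least
    accumulative cost distance over an elevation raster from a rasterized
    ice-margin source line; binomial GLM single-predictor screens with
    Bonferroni correction; and three-matrix variation partitioning based on
    adjusted D-squared. A serial founder-effect simulator and a logistic
    occurrence simulator provide synthetic data with the statistical
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    vegan,
    geosphere,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
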
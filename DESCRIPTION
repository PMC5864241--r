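Package: assemblyproc
Title: Null-Model Inference of Stochastic and Deterministic Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phylogenetic null-model framework for partitioning the ecological
    processes that assemble microbial communities along environmental
    gradients. Implements the standardized effect size of the mean nearest
    taxon distance (SES.MNTD), abundance-weighted between-community MNTD
    (betaMNTD) and its null-model z-score (betaNTI), the Bray-Curtis based
    Raup-Crick metric (RC-bray), and the five-way classification of pairwise
    community turnover into variable selection, homogeneous selection,
    dispersal limitation, homogenizing dispersal and undominated fractions.
    Includes abundance-weighted and Huisman-Olff-Fresco (HOF) niche-optimum
    estimation, Mantel correlograms for phylogenetic signal, Mantel and
    partial Mantel tests, OTU-table preparation (singleton removal,
    rarefaction, table-tree reconciliation), and a synthetic community
    generator with known assembly regimes for method validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    geosphere,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    biomformat,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
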
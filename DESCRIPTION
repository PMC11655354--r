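Package: extremesoil
Title: Resistance and Resilience of Soil Microbiomes to Extreme Climatic Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing soil-microbiome responses to extreme climatic
    disturbances (drought, flood, freeze, heat) in factorial microcosm
    experiments. Covers construction of the factorial experimental design and
    its grouped cross-validation split spaces; simulation of taxon count
    tables with planted response strategies, functional-gene profiles,
    phylogenies, covariates and replication-gradient metagenomic reads;
    community-level resistance/resilience statistics (Hellinger transform,
    rarefaction, Bray-Curtis, PERMANOVA, Mantel tests); per-taxon
    mixed-effects response-strategy classification; phylogenetic signal
    (Pagel's lambda) estimation by phylogenetic generalized least squares;
    functional-category mixed models with Dunnett contrasts and FDR control;
    origin-to-terminus replication-rate growth estimation; and prediction of
    community resistance from initial soil and climate properties with
    grouped cross-validation and partial dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    nlme,
    lme4,
    Biostrings,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phytools,
    mvtnorm,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
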
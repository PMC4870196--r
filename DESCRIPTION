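Package: phylogrid
Title: Phylogenetic Assemblage Structure of Gridded Floras and Its
    Climatic Drivers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes phylogenetic diversity, phylogenetic endemism and the
    net relatedness index of species assemblages on regular grids, derives
    current-climate and glacial-history predictors (annual water balance,
    elevation heterogeneity, temperature-change velocity since the Last
    Glacial Maximum, and least-cost postglacial accessibility measured in
    climate space), and relates metrics to predictors with simultaneous
    autoregressive spatial-error models combined by AIC-based multimodel
    averaging under collinearity-group constraints. A synthetic-data module
    generates birth-death phylogenies, gradient-structured climate surfaces,
    niche-conserved species ranges and SAR-structured responses so the whole
    pipeline can be exercised and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    phangorn,
    phytools,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
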
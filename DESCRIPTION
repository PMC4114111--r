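Package: visova
Title: Visualization of Variance for Phenome-Scale Exploratory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exploratory analysis of subjects-by-phenotypes tables through
    variance-structure models written as formula strings of the form
    'M: Y ~ X | G : (S)'. Provides group-conditioned phenotype profiles
    (means, standard errors, counts), pairwise-complete correlation
    matrices with deterministic hierarchical variable ordering, principal
    component projections, and automatic augmentation of mean/SD reaction
    time variable pairs with coefficient-of-variation, signal-to-noise and
    Fano-factor measures. Renders VISOVA parallel-coordinates displays,
    clustered correlation heatmaps and PCA group projections as
    deterministic SVG figures, assembled into static HTML reports. A
    synthetic phenome generator with planted block correlation, group
    effects and missingness makes every analysis testable offline. The
    toolkit deliberately supports hypothesis exploration only, not
    statistical hypothesis testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
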
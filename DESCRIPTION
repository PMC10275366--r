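Package: phenomet
Title: Multi-Platform Plasma Phenotyping: OPLS-DA, Effect Sizes, STOCSY and
    Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-group immunometabolic phenotyping of plasma NMR
    panels (quantified metabolites, lipoprotein subfractions, cytokines) and
    full-resolution spectra. Implements orthogonal partial least squares
    discriminant analysis (OPLS-DA) with stratified cross-validated Q2Y and
    label-permutation testing, univariate group comparison with Cliff's delta
    effect sizes and Benjamini-Hochberg false-discovery control, eruption-plot
    coordinates, statistical total correlation spectroscopy (STOCSY), and
    per-group weighted-node Spearman correlation networks across molecular
    panels. A Gaussian-copula cohort simulator with spectral peak templates
    reproduces the statistical structure the analysis assumes, so the full
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
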
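Package: pathsem
Title: Structural Equation Modeling of Perturbed Pathway Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts differentially-expressed-gene (DEG) connecting modules
    from curated pathway graphs by shortest-path fusion, reduces connector
    genes to protein-superfamily composites via first principal components,
    fits the resulting path models as observed-variable structural equation
    models (SEM) by maximum likelihood with chi-square, RMSEA, and SRMR fit
    assessment, refines poorly fitting models through modification indices
    gated by external interaction evidence, and screens two-group expression
    data for differentially expressed nodes and differentially regulated
    edges with Wald and likelihood-ratio tests. Includes a synthetic scenario
    generator for end-to-end validation and a configuration-driven pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
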
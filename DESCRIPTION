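Package: gemflux
Title: Growth-Thresholded Transcriptomics Integration for Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based modelling toolkit for tailoring genome-scale
    metabolic models to individual samples. Reads SBML Level 3 (FBC v2)
    models, applies growth-medium constraints to exchange reactions,
    converts gene expression to reaction bounds through gene-protein-reaction
    rule categories (single gene, isoenzyme sum, subunit minimum), and
    integrates those bounds sequentially, relaxing any constraint that drives
    the predicted growth rate below an experimentally measured doubling-time
    threshold. Includes flux balance analysis with an optional parsimonious
    step, single-gene knockout screens with boolean rule evaluation,
    group-wise differential-flux comparison, hypergeometric
    over-representation analysis against gene-set collections, correlation of
    in-silico knockout ratios with CRISPR gene-dependency scores, and a
    generator of analytically solvable toy models for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
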
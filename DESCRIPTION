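Package: switchFBA
Title: Dynamic Flux Balance Analysis of the Streptomyces Metabolic Switch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of the transition from growth-directed
    primary metabolism to antibiotic-producing secondary metabolism in
    Streptomyces coelicolor. Provides a genome-scale stoichiometric model
    container with SBML (Level 2 and Level 3 + fbc) input/output, a linear
    programming core for flux balance analysis with parsimonious resolution
    of degenerate optima, time-resolved FBA under dynamically varying
    nutrient constraints and a biomass-plus-antibiotics objective,
    integration of predicted flux time courses with gene expression time
    series (Pearson correlation, classification, zero-flux and essentiality
    screens), hierarchical clustering of expression profiles, and a
    synthetic-data generator with analytically known optima for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    Matrix,
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
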
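Package: fluxwindow
Title: Transcriptome-Constrained Flux Balance Analysis and Selective
    Metabolic Target Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constrains genome-scale metabolic models with RNA-seq
    expression levels (expression-proportional flux bounds), estimates
    flux distributions by biomass maximization with total-flux
    minimization (parsimonious FBA), scores the growth effect of
    throttling reactions to a fraction of their baseline flux, and
    searches heuristically for minimal reaction sets that selectively
    halve a target cell's predicted growth while sparing a reference
    cell. Includes readers for SBML (Level 3 fbc and legacy Level 2
    COBRA dialects) and a tabular model format, alternative-optima
    sampling over the optimal face, Welch-t/Benjamini-Hochberg
    differential-use statistics, and deterministic toy-network fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
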
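Package: carveflux
Title: Context-Specific Metabolic Model Carving, Flux Sampling and
    Metabolic Gene Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Carves condition-specific genome-scale metabolic models out
    of a universal model from lists of expressed genes, explores each
    carved model's steady-state flux polytope by artificial-centering
    hit-and-run and corner (random-objective vertex) sampling with
    Geweke and Raftery-Lewis convergence control, scores every reaction
    by its cumulative absolute flux correlation (RCC) and mean flux
    usage, projects those scores onto genes through gene-protein-reaction
    rules, and emits differential, enrichment-ready and plot-ready gene
    tables that add a metabolic dimension to standard transcriptomic
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
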
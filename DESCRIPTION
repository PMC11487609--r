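Package: mintnet
Title: Metabolic Interaction Networks from Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Microbiome", "Networks Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and analyzes metabolic interaction networks for microbial
    communities starting from genome-scale metabolic models (GSMMs) in SBML
    Level 3 / FBC v2 format. Detects per-model seed sets (source strongly
    connected components of the metabolite graph), computes pairwise
    competition and complementarity indices and potentially transferable
    metabolites, derives metabolic distances from parsimonious flux balance
    analysis, selects network thresholds via random-matrix-theory spacing
    tests or Z-score outlier detection, and performs topological analysis
    of the resulting networks (centralities, modules, zi-Pi hub roles,
    network intersection, bipartite microbe-metabolite export).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
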
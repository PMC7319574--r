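Package: fluxgraph
Title: Flux Graphs, Spanning Trees and k-Shortest Paths for Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless construction, analysis and layout of flux-weighted
    bipartite metabolite-reaction graphs from genome-scale metabolic models.
    Reads SBML Level 3 (fbc) and legacy COBRA-dialect models, performs flux
    balance analysis with reaction knockouts, and derives flux-weighted
    spanning trees, breadth-first complete (duplicated) trees and k-shortest
    loopless metabolic paths between any two nodes. Five deterministic layout
    algorithms (tidy tree, dendrogram, their radial variants, layered and
    force-directed) and exporters to SVG, GraphML, node-link JSON and DOT are
    included, together with deterministic toy and random model generators and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
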
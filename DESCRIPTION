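Package: rxnbool
Title: Parameter-Free Bipartite Boolean Models from Reaction-Contingency Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles reaction-contingency descriptions of signal transduction
    networks (elemental reactions, elemental states and contingencies, in the
    style of the rxncon language) into parameter-free bipartite Boolean models
    with one generic update rule per reaction target and per state target,
    optionally with source-state smoothing. Includes a synchronous
    deterministic simulation engine with exact attractor detection, an
    input-toggling analysis workflow, BoolNet-format interchange, programmatic
    builders for the minimal modification and interaction motifs with their
    expected-attractor oracles, and a model of the Sln1 branch of the yeast
    high-osmolarity glycerol (HOG) pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
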
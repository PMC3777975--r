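Package: pombeBN
Title: Boolean Threshold-Network Model of the Fission Yeast Cell Cycle
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Logical (Boolean threshold-network) model of cell cycle
    regulation in the fission yeast Schizosaccharomyces pombe. Provides the
    12-node wild-type network in both published update-rule variants
    (threshold rule with self-degradation loops, and the simplified
    default-decay rule), a synchronous update engine with trajectory
    simulation and attractor detection, exhaustive state-space enumeration
    with exact basin-of-attraction sizes, an in-silico perturbation engine
    for knockout, overexpression and link-reweighting mutants, a cell-cycle
    phase labeller and viability classifier, a curated catalog of mutant
    strains with experimental viability calls, a JSON model file format with
    lossless round-tripping, a seeded random threshold-network generator for
    property testing, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
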
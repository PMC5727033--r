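Package: adriter
Title: Ambiguous Distance Restraints and Iterative Assignment for Solid-State NMR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates labeling-scheme-aware ambiguous distance restraints
    (ADRs) from proton- and carbon-detected magic-angle-spinning NMR peak
    lists and chemical shift lists, applies redundancy-based disambiguation,
    emits hydrogen-bond and torsion restraints, and drives an iterative
    violation-analysis assignment loop over a desk-scale simulated-annealing
    restraint-satisfaction engine.  Includes a synthetic beta-barrel data
    generator (ideal sheet geometry, shift and peak simulation) so the whole
    pipeline can be exercised end to end without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
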
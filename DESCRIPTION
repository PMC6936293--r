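Package: actomaton
Title: Excitable-Medium Automata on Voxelized Actin Bundle Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of droplet-confined actin bundle
    networks modelled as three-state excitable cellular automata on a 3D
    conductive voxel grid. Builds conductive matrices from RGB confocal
    slice stacks or from synthetic network generators, stimulates the
    lattice through spherical electrodes that encode binary input strings
    as impulses, records per-electrode potential traces, extracts spike
    trains and coincidence groups, mines two-input Boolean gates from
    spike responses, characterises the device as a finite-state machine
    via weighted and pruned transition graphs and richness statistics,
    and reconstructs per-electrode Boolean functions as minimized
    disjunctive normal forms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    png,
    optparse
Config/testthat/edition: 3
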
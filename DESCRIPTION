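Package: cdftkit
Title: Conceptual-DFT Reactivity Descriptors and Drug-Likeness Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes global and local chemical-reactivity descriptors of
    Conceptual Density Functional Theory (CDFT) from quantum-chemistry
    outputs: frontier-orbital electronegativity, hardness, electrophilicity,
    electrodonating/electroaccepting powers, Koopmans-compliance diagnostics,
    condensed and grid-based Fukui functions and the dual descriptor.
    Includes readers and writers for Gaussian cube volumetric grids and a
    plain-text quantum-chemistry fixture dialect, Molinspiration-style
    drug-likeness properties (molecular weight, H-bond donor/acceptor
    counts, rotatable bonds, Ertl topological polar surface area, an
    atom-contribution logP stand-in, Lipinski Rule-of-Five violation
    counting), bioactivity-score classification, seeded synthetic-data
    generators for every input, and a pipeline that assembles the full
    analysis into a structured report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    optparse
Config/testthat/edition: 3
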
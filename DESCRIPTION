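Package: sprbind
Title: Surface Plasmon Resonance Binding Screens and Competitive Binding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for label-free small-molecule binding screens measured by
    surface plasmon resonance (SPR). Implements double referencing and DMSO
    solvent correction of Biacore-style sensorgrams, global 1:1 Langmuir
    kinetic fitting (kon, koff, KD, Rmax) with quality-control flags,
    steady-state affinity analysis, a fractional-occupancy model of two
    ligands competing for one site with a competitive versus non-competitive
    classifier, conversion between binding free energy and inhibition
    constant, and a synthetic sensorgram generator for end-to-end validation
    of the pipeline. Ships the published P2X4 receptor cannabinoid screening
    panel as a worked reference dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    deSolve,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
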
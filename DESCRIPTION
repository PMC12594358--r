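Package: phinet
Title: Graph-Transformer Estimation of Integrated Information and Major
    Complexes in Binary Boltzmann Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates small stochastic binary-node systems with Boltzmann
    transition dynamics, labels them with an exact minimum-information-
    bipartition effective-information engine (system-level integrated
    information and the maximising subsystem, the "major complex"), and fits
    a multi-task graph neural network with transformer convolutions and
    multi-head edge-aware attention that regresses the system-level
    integrated information and classifies per-node major-complex membership.
    Includes the full training recipe (composite loss, class weighting,
    disconnected-pair augmentation, k-means oversampling over the target,
    sign-momentum optimisation, early stopping), ensemble inference for
    large systems, and experiment drivers for non-extrapolative,
    extrapolative, topology-scaling and split-brain studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
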
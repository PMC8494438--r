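Package: shoalmodel
Title: Visual-Reflex Models of Emergent Shoaling in Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how two visual reflexes of larval zebrafish - the
    retinal-clutter response and global-motion integration - explain emergent group
    aggregation and alignment. Implements trajectory metrics (nearest-neighbour
    aggregation against shuffled controls, polarization, ray-cast visual occupancy
    and clutter-difference turning curves), a leaky drift-diffusion bout model for
    coherent-dot optomotor experiments, an evolutionary multiobjective fit of its
    five latent parameters against five behavioural feature curves, an agent-based
    simulator of groups of five virtual fish driven by the two reflexes, synthetic
    data generators with known ground truth, and the randomization/bootstrap
    inference toolkit used to compare groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
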
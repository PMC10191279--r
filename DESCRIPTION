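Package: dendripbpk
Title: Physiologically Based Pharmacokinetics of Dendritic Nanoparticles
    Across Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the biodistribution of a dendritic
    nanoparticle and its conjugated/released active pharmaceutical
    ingredient (API) in mouse, rat, dog and human. Implements a
    two-component (released + conjugated) nonlinear PBPK model over blood,
    liver, spleen and rest compartments with saturable tissue partitioning;
    interspecies parameter scaling (protein-binding correction, allometry,
    organ-flow ratios); in-vitro to in-vivo extrapolation of hepatic
    clearance through the well-stirred liver model; non-compartmental
    analysis of concentration-time profiles; one-at-a-time sensitivity
    analysis; a synthetic in-vivo study generator with parameter recovery;
    and a pipeline for goodness-of-fit assessment and human projection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
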
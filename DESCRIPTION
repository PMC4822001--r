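Package: conformakin
Title: Markov State Model Analysis of Protein Conformational Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete pipeline for analysing conformational dynamics of
    biomolecules from trajectory data: contact-map featurization,
    time-lagged independent component analysis (tICA), k-centers
    discretization, reversible Markov state model (MSM) estimation with
    implied-timescale lag selection, transition path theory (committors,
    reactive flux, pathway decomposition), kinetic Monte Carlo sampling of
    the estimated model, and ensemble observables (free-energy landscapes,
    NMR order parameters, torsion mutual information). Ships synthetic
    generators with analytically known ground truth (Markov chains,
    Brownian dynamics on multi-well potentials, a two-state bead polymer,
    correlated torsions, cone-restricted bond vectors) so every stage of
    the pipeline can be validated end to end. Developed around the
    conformational exchange of the calmodulin C-terminal lobe.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
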
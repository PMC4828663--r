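Package: atrialab
Title: In Silico Left Atrial Fibrillation and Radiofrequency Ablation Laboratory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates persistent atrial fibrillation on a synthetic fibrotic
    left-atrial surface and evaluates virtual radiofrequency-ablation
    strategies. Provides a synthetic atrial geometry generator (triangulated
    surface with pulmonary-vein ostia, fiber field and an
    enhancement-likelihood map), stochastic interstitial-fibrosis modeling by
    fiber-weighted edge selection and edge splitting, the
    Courtemanche-Ramirez-Nattel human atrial ionic model with persistent-AF
    electrical remodeling, a monodomain finite-element reaction-diffusion
    solver on triangulated surfaces, phase-singularity detection and tracking
    from Hilbert-transform phase maps, construction of pulmonary-vein
    isolation, linear, shape-based and activation-streamlining lesion sets,
    and outcome classification with regional correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
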
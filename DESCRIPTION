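Package: mitovolt
Title: Quantification of Intramitochondrial Membrane-Potential Heterogeneity
Version: 0.1.0
Authors@R: person("Mitovolt", "Developers", email = "mitovolt@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify sub-organelle heterogeneity of the
    mitochondrial membrane potential from two-channel time-lapse
    fluorescence imaging of potentiometric dyes (TMRE/TMRM/Rho123) and
    structural membrane dyes (NAO/MitoTracker Green). Provides Nernstian
    conversion of intensity ratios into millivolt differences between
    cristae, inner boundary membrane, matrix and detached vesicles;
    crista detection along the organelle axis; flicker decomposition into
    potential-dependent and potential-independent dye fractions;
    per-crista potential tracking over time; and laser-induced
    depolarization-wave analysis. A forward simulator renders
    ground-truthed phantom image stacks (capsule geometry, Nernstian dye
    partitioning, Gaussian optics, Poisson noise) so every analysis stage
    is verifiable by parameter recovery without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
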
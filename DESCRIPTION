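Package: bdslide
Title: Brownian Dynamics of Coarse-Grained Protein Sliding Along DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Brownian-dynamics simulator for a DNA-binding
    protein diffusing along double-stranded DNA. Provides builders for the
    four-bead-type coarse-grained DNA/protein model, an analytic force field
    (harmonic bonds, angles and torsions, half-harmonic excluded volume and
    screened DLVO electrostatics), configuration-dependent hydrodynamic
    interactions through the Rotne-Prager-Yamakawa tensor, a second-order
    Runge-Kutta Brownian-dynamics integrator with correlated random
    displacements, umbrella sampling with WHAM reconstruction of
    protein-DNA binding free energies, rigid-particle bead-model
    hydrodynamic theory, the Bagchi-Blainey-Xie model of rotation-coupled
    sliding, and trajectory analysis (1D diffusion coefficients,
    rotation-translation coupling, hopping detection, persistence length).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
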
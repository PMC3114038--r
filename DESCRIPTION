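Package: rigidbd
Title: Rigid-Body Brownian Dynamics of Protein Solutions and Hydrophobic
    Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Atomic-detail implicit-solvent rigid-body Brownian dynamics for
    many-protein systems. Interaction free energies (screened electrostatics,
    electrostatic and non-polar desolvation, soft-core repulsion) are mapped
    onto regular grids per species and evaluated by trilinear interpolation;
    N rigid bodies are propagated with the Ermak-McCammon algorithm in a
    periodic box, optionally above a hydrophobic graphite (HOPG) layer with
    reflective top. Includes trajectory analyses for oligomerization
    (independent-atomic-contact encounter criterion, oligomer fractions,
    tetramer composition typing, GROMOS-style conformational clustering,
    atomic contact probabilities) and spatial distributions (radial
    distribution functions and surface-normal density profiles), together
    with a synthetic generator of amphipathic toy proteins for end-to-end
    testing without external structures or solvers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
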
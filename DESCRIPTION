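Package: condensekit
Title: Trajectory Analysis for Biomolecular Condensate Simulations
Version: 0.1.0
Authors@R: person("Condensekit", "Developers", role = c("aut", "cre"),
    email = "maintainers@condensekit.dev")
Description: Analysis toolkit for all-atom simulations of phase-separating
    multidomain proteins. Provides summed heavy-atom residue contact maps
    with intra/intermolecular channels, residue-type interaction rankings,
    an angle-distance pair correlation function for sp2-plane (pi-pi)
    stacking, chain-dimension metrics including a convex-hull hydrodynamic
    radius, slab density and ion-partition profiles, flat-bottom
    hydrogen-bond restraints, and a seed-reproducible synthetic-conformation
    generator with planted structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
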
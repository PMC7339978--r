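Package: channelflux
Title: Channel Geometry, Permeation Statistics, and Osmotic Flux Analysis
    for Aquaglyceroporins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to compare water and glycerol transport in
    aquaglyceroporin channels from atomic structures, solute trajectories,
    umbrella-sampling data, and oocyte swelling assays. Computes pore-radius
    profiles, superpositions, side-chain dihedrals and buried surface areas
    from PDB structures; orientation order parameters, per-residue
    flexibility, binding-site visits, residence times and translocation
    events from solute tracks; reconstructs free-energy profiles by the
    weighted histogram analysis method (WHAM) and converts permeation
    statistics into single-channel permeability coefficients; estimates
    osmotic water permeability (Pf) from oocyte swelling recordings and
    simulates the coupled water/solute flux that produces paradoxical
    swelling in glycerol baths. A synthetic-data module generates every
    input with known ground truth (overdamped Langevin dynamics on a
    double-barrier potential of mean force, umbrella-biased sampling,
    analytic channel fixtures, and oocyte volume traces) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
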
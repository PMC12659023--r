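Package: poreflux
Title: Ionic Current, Electroosmotic Flow and Density-Map Analysis for
    Nanopore Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("poreflux", "developers", email = "poreflux@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for non-equilibrium molecular dynamics
    of biological nanopores in electrolyte solution. Computes windowed ionic
    currents from charge-weighted axial displacements, species-resolved
    (cation/anion) current decompositions, electroosmotic water flux, block
    average and replica error estimates, conductance and electrolyte
    conductivity from current-voltage curves, cylindrical (r, z) ion and
    water density maps with an L2 map-distance statistic for force-field
    ensemble comparison, and viscosity/conductivity rescaling of transport
    observables. Includes a drift-diffusion Brownian trajectory generator
    with closed-form transport expectations so every pipeline stage is
    testable without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
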
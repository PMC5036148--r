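Package: nanoheat
Title: Thermal Transport Analysis at Graphene-Water-Lipid Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for heat dissipation across nanomaterial-water-
    membrane interfaces. Computes slab mass-density profiles and intercalated-
    water descriptors (layer thickness, first-peak mass), Einstein-relation
    diffusion coefficients from mean-square displacement, interfacial (Kapitza)
    thermal conductance from pulse-relaxation temperature series, and critical
    heating power from temperature-rise curves. Includes the analytical serial-
    resistor Fourier model for steady-state temperature profiles and lumped-
    parameter transient sheet temperature, with least-squares parameter
    recovery, plus a synthetic molecular-dynamics surrogate generator (layered
    density sampler, Brownian trajectories, stochastic 1-D layered heat-
    conduction lattice) so the full pipeline runs at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
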
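Package: cntrates
Title: Classical Nucleation Theory Rate Curves from Simulation Observables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes classical-nucleation-theory (CNT) nucleation and
    crystal-growth rate curves for model molecular systems from simulation
    observables. Implements the capillary fluctuation method (CFM) for the
    solid-liquid interfacial stiffness from interface height-fluctuation
    spectra, Steinhardt bond-orientational order parameters at molecular
    geometric centers for solid/liquid classification, the entropy-integrated
    crystallization driving force with melting boundary conditions, the
    Turnbull temperature scaling of the interfacial free energy,
    Vogel-Fulcher-Tammann fits of the diffusion coefficient, and
    mean-square-displacement diffusion estimation. A synthetic-data module
    generates every pipeline input with known ground truth (equipartition
    capillary spectra, biphasic crystal/liquid configurations, enthalpy and
    volume curves with melting discontinuities, Brownian trajectories,
    VFT-shaped diffusion series) so that each stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'units.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io-structure.R'
    'io-series.R'
    'molecule.R'
    'synthetic.R'
    'order.R'
    'capillary.R'
    'thermo.R'
    'dynamics.R'
    'rates.R'
    'pipeline.R'
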
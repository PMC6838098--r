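Package: invadefem
Title: Finite-Element Modelling of Invasive-Species Spread with
    Polynomial-Chaos Uncertainty Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the spatio-temporal spread of an invasive species with
    a Fisher-KPP type advection-diffusion-reaction equation on geography-aware
    triangular meshes. Provides SRTM HGT elevation ingestion and synthetic
    terrain generation, data-driven mesh generation with gradient-driven
    red-green refinement, P1 Lagrange finite-element assembly, semi-implicit
    (IMEX) time stepping with arrival-time maps and probe time series, and a
    data-driven arbitrary polynomial chaos layer (moment-based Gaussian
    quadrature, Smolyak sparse grids, pseudo-spectral projection, surrogate
    Monte Carlo) that propagates parametric uncertainty in the diffusion
    coefficient and carrying-capacity scale into density fields and arrival
    times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    mgcv,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
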
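Package: seedwave
Title: Inverse Estimation of Dielectric Loss Factor and Moisture
    Diffusivity During Microwave Drying of Lentil Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled transient heat and moisture transfer model of a single
    lens-shaped lentil seed under microwave heating, solved with linear
    triangular finite elements on a two-dimensional axisymmetric mesh, and an
    inverse-simulation workflow that estimates the seed's dielectric loss
    factor and effective moisture diffusivity as functions of temperature and
    moisture content. The estimation proceeds in two stages: decoupled
    lumped-capacitance fits driven by five-harmonic Fourier smoothing of the
    measured series supply initial coefficient guesses, which a
    multi-objective goal-attainment refinement then polishes against measured
    surface-temperature and moisture-content drying curves. Includes
    thermophysical property correlations for lentil, packaged coefficient
    tables, a synthetic drying-record generator for end-to-end
    parameter-recovery studies, and plotting and broom-style tidier methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
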
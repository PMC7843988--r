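Package: teoim
Title: Thermo-Elastic Optical Indicator Microscopy Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for thermo-elastic optical
    indicator microscopy (TEOIM) of microwave near fields around aqueous
    solutions. Provides a Debye-plus-conductivity dielectric absorption model
    with microwave penetration depth, a physics-based synthetic generator of
    polarimetric analyzer images (parametric near field, spectral plane-stress
    thermoelastic solve, Mueller-chain rendering with frame-averaged camera
    noise), the second-derivative inverse reconstruction of the
    microwave-induced heat-source distribution from linear-birefringence
    images, and concentration-response calibration: replicate statistics,
    exponential intensity fits, minimum detectable concentration curves, and
    frequency-sweep contrast analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
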
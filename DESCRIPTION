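Package: fsmotion
Title: Arrival-Circle Analysis of Sprint Motion in Player Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating the Fujimura-Sugihara equation-of-motion
    model of sprinting against player tracking data. Provides the model's
    closed-form solution and arrival-circle geometry, a numerical integrator
    for the variable-coefficient extension, a seeded synthetic tracking-data
    generator with realistic walk/jog/sprint structure, velocity and
    mean-squared-displacement kinematics, velocity-frame arrival-point heat
    maps with isolated-cell filtering and extent-based circle estimation,
    and inversion of the heat-map geometry into the model's kinetic
    parameters (drag-to-mass ratio alpha and terminal speed V_max).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
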
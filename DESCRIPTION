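Package: exclusim
Title: Probiotic-Pathogen Competitive Exclusion Modelling and Disinfection
    Efficacy Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling competitive exclusion of pathogens by
    probiotic consortia on surfaces and in liquid culture. Implements a
    generalized Lotka-Volterra (gLV) community model with carrying-capacity
    normalized antagonism terms, ODE integration, extinction-time diagnostics,
    bisection calibration and consortium experiments; interaction-coefficient
    inference by bounded multi-start nonlinear least squares with residual
    resampling bootstrap; a spatially explicit stochastic agent-based model of
    four microbial guilds with metabolite secretion, explicit-stencil
    diffusion, Hill-function cross-feeding, probabilistic antagonism and
    biofilm transition; disinfection-trial statistics (colony-forming-unit
    enumeration from serial dilutions, log and percentage reduction, pooled
    t-tests, inhibition-zone summaries, formulation concentration arithmetic);
    and seeded synthetic-data generators for coculture time series, plate
    counts, storage-stability and surface-survival curves, and
    inhibition-zone tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
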
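Package: gravisort
Title: Physics and Simulation of a Buoyancy-Counterforce Gravitaxis Sorter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the physics of sorting swimming nematodes by gravitaxis
    competence in a multi-column fluidic device filled with a liquid slightly
    denser than the animals. Provides the overdamped Stokes force balance and
    the scalar estimators derived from it (reduced weight, drag coefficient,
    Stokes radius, propulsive thrust, apparent diffusion, Reynolds number), a
    two-dimensional stream-function-vorticity Stokes solver for one column
    unit cell of the device with vortex and flux diagnostics, a seeded
    run-and-tumble versus directed-thrust particle simulation that classifies
    exits through the top and bottom conduits, sorting statistics
    (efficiency, specificity, multi-round cumulative efficiency, a logistic
    model of efficiency decline, summary-statistics t-tests), and synthetic
    track and count generators so every estimator can be exercised without
    external data. A command-line entry point wraps the main workflows.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
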
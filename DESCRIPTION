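Package: esnmort
Title: Echo State Network Projections of Temperature-Driven Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links gridded monthly-maximum 2m temperature fields to monthly
    all-cause mortality rates with an echo state network (leaky-integrator
    reservoir, ridge-regression readout), following the reservoir-computing
    practice of fixed random input and recurrent weights. Includes
    preprocessing of gridded netCDF temperature stacks and deaths/population
    tables, ensemble training with seeded initialization, test-period
    evaluation, mortality projection under +2K/+4K warmer-world scenario
    inputs, and a seeded synthetic storyline/mortality generator so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    RSpectra,
    ncdf4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
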
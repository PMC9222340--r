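Package: extrusim
Title: One-Dimensional Global Modelling of Twin-Screw Extrusion of Starchy Food Melts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of co-rotating twin-screw extrusion of starchy and
    leguminous food melts with a one-dimensional global flow model. Screw and
    die elements are described by elementary drag/pressure flow models
    (C-chamber formulation), the melt by an Ostwald-de Waele power law whose
    consistency and flow index depend on temperature, moisture content and
    specific mechanical energy (SME). A backward shooting solver couples the
    pressure, temperature and SME profiles from the die to the melting section
    and returns die-exit temperature, SME, pressure and viscosity. The package
    ships a viscosity parameter database for maize, potato, breakfast-cereal,
    pea-flour and wheat-bran melts, tools to fit viscosity parameters from
    rheometry data, operating-chart sweeps with feasible-region extraction,
    and product-feature correlation models (fit, predict, invert) for
    extruded-food design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    minpack.lm,
    optparse
Config/testthat/edition: 3
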
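Package: sodscreen
Title: Screening Nanomaterials for Superoxide Dismutase-Like Catalytic Activity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for predicting and screening the superoxide dismutase
    (SOD)-like activity of nanomaterials from electronic-structure and
    surface-adsorption descriptors. Implements an energy-level criterion
    based on frontier-level positions relative to the superoxide dismutation
    redox window, and an adsorption-energy criterion based on the Boltzmann
    partition fraction of the target dismutation among five competing surface
    reactions. Includes reaction free-energy models with pH and temperature
    dependence, adsorption-energy linear scaling relations with refitting,
    electrode reference-potential conversions, a three-stage high-throughput
    screening funnel over materials-property tables, a synthetic table
    generator for testing, CSV/JSON input and output, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
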
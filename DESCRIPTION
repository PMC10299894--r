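Package: monowet
Title: Wetting Thermodynamics of Lipid Monolayer Adsorption on Solid Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a lipid monolayer stably adsorbs to a
    solid surface from wetting thermodynamics. Implements a two-state
    (adsorbed monolayer versus bulk bilayer) free-energy model driven by the
    substrate contact angle, the adsorption contact angle and equivalent
    air-water contact angle derived from it, and a Zisman-type adhesion-tension
    model for water/alcohol solvent exchange. Also provides the two
    molecular-dynamics post-processing steps that feed the model: contact-angle
    extraction from 2-D density fields of sessile cylindrical droplets (with
    extrapolation to the macroscopic angle) and work-of-adhesion evaluation by
    integration of pressure-distance curves. Seeded synthetic-data generators
    with known ground truth make the whole pipeline testable without
    simulation output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
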
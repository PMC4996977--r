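Package: larvadrift
Title: Biophysical Coral Larval Dispersal and Seascape Connectivity Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-dimensional surface-ocean Lagrangian larval dispersal model
    with stochastic larval biology (competency ramp, daily mortality, maximum
    pelagic duration), habitat-cell and ecoregion connectivity accounting,
    cross-barrier connection detection, and comparison of modelled dispersal
    with pairwise genetic differentiation (F'ST) via Mantel tests. Includes a
    synthetic-data module that generates ENSO-modulated equatorial current
    systems with mesoscale eddies, reef seascapes split by an open-ocean
    dispersal barrier, and genetic differentiation matrices coupled to
    dispersal probability, so the full pipeline can be exercised and tested
    without external ocean-reanalysis or reef-survey downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
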
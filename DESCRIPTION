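Package: carbonscape
Title: Terrestrial Ecosystem Carbon Bookkeeping and Patch-Generating
    Land-Use Simulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Four-pool carbon-density bookkeeping over categorical
    land-cover maps, area-flow transition accounting with map-agreement
    metrics, Markov-chain land demand projection, random-forest land
    suitability surfaces, a demand-driven patch-generating cellular
    automaton, and entropy-weight multi-criteria sustainability scoring.
    Ships a synthetic-landscape generator with planted driver effects so
    the whole pipeline can be exercised without external rasters, plus
    reference carbon-density and area tables for the Guizhou karst
    case study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
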
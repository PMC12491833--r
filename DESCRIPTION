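Package: lucattr
Title: Attribution of Land-Use-Change and Agricultural-Management
    Emissions to Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A spatially explicit bookkeeping pipeline that attributes
    greenhouse-gas emissions from land-use change and agricultural
    management to 16 crop categories plus pastureland on a gridded
    5-year time series. Converts aboveground carbon density to per-cell
    stocks, detects and classifies land-use transitions into six
    categories, labels emission versus sequestration events, routes
    seven agricultural-management emission sources through their
    attribution rules (proportional to crop-area increase, proportional
    to aboveground residue, or natively crop-specific), and assembles a
    region by crop by step by source CO2-equivalent emission ledger.
    Derives marginal and total emission footprints, emission
    intensities, land requirements, their decomposition identity, a
    three-cluster crop-region classification, and a first-order soil
    carbon share. Includes a seeded synthetic-world generator with a
    closed-form expected ledger so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ncdf4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'attribution.R'
    'carbon_stock.R'
    'geometry.R'
    'lucattr-package.R'
    'management.R'
    'metrics.R'
    'pipeline.R'
    'raster_io.R'
    'synthetic_world.R'
    'transitions.R'
    'vocabularies.R'
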
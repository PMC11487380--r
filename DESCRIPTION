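Package: luccarbon
Title: Land-Use-Change Simulation and Terrestrial Carbon Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for categorical land-cover analysis on regular grids:
    CORINE-to-IPCC class reclassification, transition-probability
    estimation by cross-tabulation, averaged-Markov quantity projection
    with cellular-automata contiguity allocation, Pontius-style map
    agreement decomposition and kappa variants, carbon-pool construction
    from forest growing stock and inventory defaults, carbon storage and
    sequestration accounting with CO2 equivalence and discounted economic
    valuation, and a seeded synthetic-landscape generator so the whole
    pipeline runs without external downloads. Bundled reference tables
    reproduce a published multi-decadal case study for Calabria (Italy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
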
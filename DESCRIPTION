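Package: floralres
Title: Floral Resources for Pollinators from Transect, Phenology, and Nectar Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies what a mass-flowering crop offers pollinators. Estimates
    open-flower density from plotless point-transect distance records (joint
    point-to-flower and flower-to-neighbour distances with a clustering
    correction, truncation-radius selection, and bootstrap confidence limits),
    integrates flower-cover and pollinator-visitation time series into season
    totals, converts microcapillary nectar measurements into per-flower and
    per-hectare sucrose budgets and honey-bee colony support, and performs the
    gross-return and break-even arithmetic for comparing an oilseed forage crop
    with commodity-crop returns. Includes a synthetic field simulator (Poisson
    and Thomas-cluster flower patterns, transect sampling, phenology and nectar
    records) so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
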
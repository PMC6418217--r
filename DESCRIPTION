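Package: glacierLOAC
Title: Biogeochemical Budgets and Process Models for Glacier-Fed Arctic Watersheds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for watershed-scale biogeochemistry along a glacierized
    land-to-ocean aquatic continuum: snow-core water equivalents and
    conservative-tracer partitioning of snowmelt into sublimation and runoff;
    rating-curve (log-linear) constituent load estimation with Duan smearing
    and bias-based model selection; annual lake input-output nutrient mass
    balances with source/sink classification; inverse modelling of sediment
    oxygen microprofiles as piecewise-constant consumption zones; water-column
    and stoichiometric summaries (Secchi-derived light extinction, DIN:TP
    nutrient limitation, carbonate speciation); and Hellinger-transform
    PCA/RDA community ordination with variance-inflation screening and
    AIC forward selection. A seeded synthetic-watershed generator provides
    ground-truth scenarios for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
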
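Package: reefcarb
Title: Carbonate Budgets and Reef-Accretion Potential for Upwelling and
    Non-Upwelling Coral Reefs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Census-based carbonate-budget models for eastern tropical
    Pacific coral reefs. Converts point-intercept benthic surveys, coral
    out-plant buoyant-weight time series, grazer (sea urchin, parrotfish,
    pufferfish) densities, and reef-core compaction summaries into gross
    carbonate production, component bioerosion rates (macroborers,
    microborers, boring sponges, urchins, parrotfish, corallivorous
    pufferfish), net carbonate production, and reef-accretion potential
    (RAP). Fits coral-cover threshold models for net-positive budgets and
    for keeping up with sea-level-rise scenarios localized from tide-gauge
    trends, and ships a synthetic-data generator that emulates the survey
    designs so the whole pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
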
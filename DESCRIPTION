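Package: chillsuit
Title: Winter Chill Accumulation, Weather-Station QC and Stone-Fruit
    Varietal Suitability
Version: 0.9.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for agroclimatic decision support in temperate fruit
    growing. Validates hourly weather-station records with a six-level
    quality-control cascade, accumulates winter chill under the Chilling
    Hours, Utah Cold Unit and Dynamic (Chill Portion) models, estimates
    dormancy start and end-of-count dates, classifies station
    climatologies into five Mediterranean climate zones, detects extreme
    temperature events and binomial frost risk for earliness groups, and
    recommends which stone-fruit varietal groups are climatically
    suitable at a site. Includes a seed-deterministic synthetic weather
    generator for the five zones with injectable quality violations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
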
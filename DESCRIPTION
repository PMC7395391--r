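Package: ripcarbon
Title: Carbon Accounting for Rangeland Riparian Restoration
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies carbon sequestration from streambank revegetation
    in rangeland riparian zones. Converts stem inventories to aboveground
    and belowground tree/shrub carbon with group-level allometric
    equations, computes soil carbon and nitrogen stocks on an equivalent
    soil mass basis with mass-weighted property profiles, fits a
    von Bertalanffy growth curve and a linear soil-accumulation trend to
    chronosequence data with bootstrap or posterior uncertainty, builds
    age-indexed carbon projection tables per riparian landform, and scales
    per-hectare densities to county totals with carbon dioxide equivalent
    conversion and valuation. Includes a synthetic chronosequence
    generator so every pipeline stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
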
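Package: strawinv
Title: Bottom-Up Wheat Straw Inventory: Nutrient Returns and Open-Burning Emissions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds city-level bottom-up inventories of wheat straw resources
    from activity data (planting acreage and grain yield per hectare). Fits
    regional exponential grain-to-straw yield models, scales per-hectare straw
    yield to city totals, partitions straw by field-management mode (recycling,
    open burning, removal), computes nitrogen, phosphorus and potassium returns
    to cropland and six gaseous-pollutant emissions from open burning, and
    propagates coefficient uncertainty by Monte-Carlo simulation with 5th-95th
    percentile reporting. Includes a synthetic-data generator emulating the
    statistical structure of field-experiment and statistical-yearbook inputs,
    so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
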
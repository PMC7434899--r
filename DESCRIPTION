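Package: watneeds
Title: Gridded Green and Blue Crop Water Requirements from a Daily Soil
    Water Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes crop-specific green (rain-fed) and blue (irrigation)
    consumptive water requirements on a WGS84 latitude-longitude grid by
    solving a daily vertical soil water balance in the root zone. Daily
    crop coefficient curves follow the FAO-56 four-stage convention scaled
    to regional planting and harvest dates; actual evapotranspiration is
    reduced by a linear soil-moisture stress coefficient below the readily
    available water; deep percolation ramps linearly with moisture between
    the readily and totally available water; a fixed share of precipitation
    is partitioned to surface runoff. Green water is the stressed actual
    evapotranspiration and blue water is the unstressed-minus-stressed
    difference on irrigated land, summed over each month of the growing
    season. Includes a three-year spin-up protocol, multi-season calendar
    consolidation, NetCDF-4 grid input/output, a seeded synthetic forcing
    generator for fully offline testing, and sensitivity drivers for the
    initial soil moisture and the off-season crop coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
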
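Package: sfcsample
Title: Space-Filling-Curve Sampling and Model-Based Biomass Estimation
    for Spaceborne Lidar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns an irregularly distributed set of spaceborne-lidar
    forest-height shots into a defensible simple random sample by ordering
    the pixels of a forest mask along a fractal space-filling (Peano)
    curve, tessellating the resulting number line into the smallest
    equal-length (hence equal-area) segments that each contain at least
    one shot, and drawing one shot at random per segment. Provides the
    model-based estimator of mean aboveground biomass density built on a
    polynomial height-biomass regression, with a two-component variance
    that separates sampling uncertainty from model-parameter uncertainty,
    plus a synthetic-data generator and Monte Carlo machinery to validate
    the estimator's frequentist coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
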
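Package: melanoclim
Title: Colour Lightness of Butterfly Assemblages Along Climatic Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for testing the thermal melanism hypothesis at the
    assemblage level. Extracts colour lightness (mean of the red, green and
    blue channels over a body-and-proximal-wing region of interest) from
    specimen images, aggregates species traits into community means on an
    equal-area grid via range-polygon rasterization, summarises insolation,
    temperature and humidity rasters per grid cell, and fits a
    linear/quadratic regression battery with delta r-squared shape
    classification, spatial generalized least squares with a Gaussian
    correlation structure, and Tukey HSD side contrasts. Includes a seeded
    synthetic-world generator (climate fields, species pools with a known
    lightness-temperature coupling, niche-band ranges, rendered specimens)
    so the whole pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    nlme,
    png,
    tiff,
    jsonlite,
    tibble,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
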
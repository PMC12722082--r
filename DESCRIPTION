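Package: foodaccess
Title: Culturally Appropriate Food Access Measures and Spatial Regression of Area-Level Diabetes Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the relationship between neighbourhood access
    to culturally appropriate food and area-level diabetes rates. Implements a
    rule-based classifier of food outlets into restaurant/grocery and
    AAPI/non-AAPI groups, six tract-level ethnic-store access measures plus a
    supermarket-distance share, suppression-aware downscaling of subregional
    disease case counts to tract rates, queen and k-nearest-neighbour spatial
    weights, Moran's I with normal and permutation inference, ordinary least
    squares and maximum-likelihood spatial lag regression, and a synthetic
    county generator so the full pipeline can be exercised and validated
    without restricted data.
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
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    yaml,
    optparse
Config/testthat/edition: 3
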
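Package: edgebias
Title: Edge-Effect Bias in Food Environment Accessibility and Availability Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo evaluation of edge-censoring bias in spatial
    availability and accessibility measures used in built food environment
    research. Simulates clustered food-outlet patterns on the unit square by
    thinning uniform proposals against a Gaussian-kernel cluster intensity,
    computes availability (outlet counts per tract cell) and accessibility
    (inverse-distance cumulative opportunity and nearest-outlet distance)
    measures at a mesh of evaluation sites, and contrasts measures computed on
    the full window against measures restricted to an internal guard-area
    subset, summarising percentage error and absolute bias by distance to the
    guard boundary. Includes profile and contour visualisations of the error
    fields.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
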
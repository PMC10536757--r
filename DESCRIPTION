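Package: streetscape
Title: Built-Environment Features from Street-Level Imagery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measures outdoor-play-relevant built-environment features from
    street-level imagery. Provides interval sampling of points along a street
    network with cardinal-direction image requests, per-pixel semantic
    segmentation summaries over the 19-class street-scene palette with the
    cyclist/vehicle class collapsing, Manhattan (L1), network-distance and
    Euclidean buffer aggregation to zones, cross-validated regression models
    (linear, gradient-boosted trees, support vector machines) with buffer-size
    sweeps and cross-city transfer evaluation, hexagonal-grid point thinning,
    and a fully synthetic city generator so the complete pipeline runs and is
    tested without external imagery or API access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    e1071,
    xgboost,
    yaml,
    stats,
    tools,
    utils
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
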
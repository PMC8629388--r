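Package: spatannot
Title: Scale-Explicit Spatiotemporal Environmental Annotation of Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attaches environmental summaries (mean, standard deviation, valid
    pixel count) from gridded layer time series to point occurrence records,
    with user-controlled spatial buffers (a radius in meters around each
    record) and temporal buffers (trailing day windows). Includes a layer
    catalog over plain-text rasters, a geohash-based clustering planner that
    minimizes redundant scene retrievals, spatial coarsening and temporal
    compositing utilities, grain-specific versus grain-agnostic comparison
    metrics, a synthetic landscape generator for testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
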
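Package: cortexgrid
Title: Grid-Cell Location Codes, Displacement Cells and Sensorimotor
    Object Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale simulator of location-based cortical
    computation.  Modular grid-cell location codes over 2D space are
    updated by path integration, combined across modules into
    high-capacity location representations, and differenced
    module-by-module into displacement codes that express both movement
    vectors and the relative placement of objects.  Objects are learned
    as maps from discretized locations to sensed features, composed via
    displacement vectors (including recursive composition), and animated
    by high-order sequences of displacements.  Sensorimotor recognition
    maintains a union of (object, location) hypotheses per cortical
    column, narrows it by movement and sensation, and lets multiple
    columns vote to consensus.  Includes synthetic-world generators,
    capacity / recognition / navigation experiments, tidy() and glance()
    methods for all result types, and ggplot2 autoplot() figures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
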
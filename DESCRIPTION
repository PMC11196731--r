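Package: camtrapdecide
Title: Cost, Carbon and Observer-Accuracy Decision Support for
    Camera-Trap Monitoring Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision support for wildlife monitoring programs that use
    camera traps. Compares the lifetime cost and vehicle carbon emissions
    of three program designs (manual SD-card retrieval with manual image
    classification, manual retrieval with AI classification, and
    4G-connected cameras with AI classification) under a transparent
    additive cost model. Aggregates timestamped per-image classifications
    into three-image trigger sets and gap-merged detection sequences,
    scores human and machine observers (type I and type II errors) at the
    image and sequence level, computes confidence-threshold review
    workloads and per-decile confidence histograms, and simulates
    classification-record tables with the statistical structure of a large
    feral-cat eradication case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
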
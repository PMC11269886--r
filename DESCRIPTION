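Package: gapelimit
Title: Ingestion Success of a Gape-Limited Snake Predator on Avian Prey
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for radio-telemetry studies of gape-limited
    predation: cause-of-mortality classification of tracked fledglings,
    estimation of the ingestion-failure ("slimed") rate with a Wilson score
    interval, logistic regression of ingestion outcome on prey mass fitted by
    iteratively reweighted least squares, a seeded bootstrap comparison of
    successful-ingestor body size against the endotherm-attracted predator
    population, relative prey mass (RPM) summaries with a Gaussian linear
    model, and a synthetic-data generator that emulates the statistical
    structure of the field data so every stage is testable without them.
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
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
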
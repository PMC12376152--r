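Package: vmscore
Title: Virtual Motor Scores and Motor Level Recalculation for ISNCSCI Exams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the International Standards for Neurological
    Classification of Spinal Cord Injury (ISNCSCI). Predicts "virtual" motor
    scores for spinal segments without clinically testable key muscles from
    same-segment sensory scores (consensus clinical rule, linear and random
    forest regression over four sensory feature sets), enumerates the
    predictors as integer lookup tables, recalculates motor levels from
    virtual plus examined motor scores, and quantifies the deviation from
    the rule-based motor level over a cohort. Includes a seeded generator of
    synthetic EMSCI-like exam cohorts, grouped cross-validated model
    benchmarking, CSV/JSON/YAML input-output and a small command line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
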
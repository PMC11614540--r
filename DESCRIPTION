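Package: locomotr
Title: Cross-Cultural Locomotor Versatility with Phylogenetic Correction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for cross-cultural analysis of hunter-gatherer locomotor
    versatility: validation and aggregation of quote-level ethnographic
    locomotor codes into society-level traits, phylogenetic-isolation
    weighting on a time-calibrated society supertree, weighted-resampling
    correction of trait proportions (a control for Galton's problem),
    ecological, functional-domain and gender summary statistics, and a
    seeded synthetic-data generator that emulates the ethnographic
    documentation process so the whole pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
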
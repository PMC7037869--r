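Package: dematelwsm
Title: Hybrid DEMATEL and Weighted-Sum Ranking of Hospital Departments by
    Cross-Infection Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision support for rearchitecting healthcare facilities to
    reduce nosocomial infection risk. Aggregates rank-weighted expert
    judgments into consensus matrices, runs a DEMATEL (Decision-Making Trial
    and Evaluation Laboratory) analysis of cross-infection influence among
    departments (total-relation matrix, prominence R+C, relation R-C,
    cause/effect classification), converts the result into a 0-100
    infection-risk criterion, and merges it with managerial criteria in a
    modified weighted-sum model to rank departments for elimination or
    hygiene reinforcement. Includes a synthetic case generator, readers and
    writers for the CSV/JSON interchange formats, and fixtures transcribing
    a published hospital case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
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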
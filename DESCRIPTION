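Package: vnet
Title: Social Network Inference for Induced-Cooperation Field Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and tests animal social networks from behavioural event
    logs collected in field experiments where a group is split into two
    cooperation classes that must join up at paired feeders to obtain food.
    Provides bout segmentation of timestamped observation streams,
    proximity/affiliation/cooperation association matrices, social
    differentiation estimates corrected for binomial sampling variance with
    bootstrap standard errors, presence-constrained permutation tests of
    preferred or avoided association, masked Mantel and partial Mantel tests
    of partner-choice drivers (sex, age, rank, relatedness), David's Score
    dominance indices, Ward-linkage cluster trees with cophenetic validation,
    Newman modularity communities, a synthetic-data generator with known
    ground truth for power and calibration studies, and a one-command
    analysis pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
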
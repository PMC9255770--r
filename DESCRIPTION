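Package: mazeddm
Title: Weighted-Constraint Drift-Diffusion Modeling of Maze Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analyzing initial path choices in grid-maze planning
    tasks with a weighted constraint satisfaction drift-diffusion model.
    Provides maze trial construction and enumeration with path-advantage
    bookkeeping, response-time standardization and trial exclusion rules,
    first-passage-time likelihoods with inter-trial variability in drift and
    starting point, Monte-Carlo cross-validated model comparison across
    constraint-weighting variants, accuracy-group analyses with a
    random-split permutation baseline, and a synthetic-cohort generator for
    parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    lme4
Config/testthat/edition: 3
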
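Package: standassoc
Title: Interspecific Association and Spatial Structure of Stem-Mapped
    Forest Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stage-stratified analysis of interspecific association and
    fine-scale spatial structure in fully stem-mapped forest plots.
    Computes species importance values (relative density, frequency and
    dominance), all-pairs 2x2 quadrat co-occurrence tests with the
    Yates-corrected chi-square statistic and the piecewise AC association
    coefficient, Schluter's variance-ratio test of overall multi-species
    association, and the nearest-neighbour uniform angle index with
    buffer-zone edge correction. Includes a seeded generator of synthetic
    stem maps with known spatial pattern (Poisson, Thomas cluster, hard-core
    inhibition), reverse-J diameter structure and controllable pairwise
    habitat associations, so every stage of the pipeline can be validated
    against a known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
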
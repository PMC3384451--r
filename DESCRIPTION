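Package: crowdFBA
Title: Flux Balance Analysis with Molecular Crowding for Metabolic Switching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modeling with a molecular-crowding
    constraint (FBAwMC). Solves flux balance problems in which the total
    enzyme volume that sustains the flux distribution is capped by a budget
    V_prot, builds crowding-coefficient distributions from enzyme turnover
    numbers and molar masses, and runs the ensemble experiments that explain
    why some microbes switch off high-yield metabolism at fast growth while
    others show overflow metabolism: random crowding-coefficient sampling,
    growth curves, yield-distribution mode counting, exchange knockouts,
    NADH-oxidase overexpression mimicry, and V_prot fitting to observed
    growth data. Includes a five-reaction fermentation/respiration fixture,
    synthetic network and turnover-table generators, and readers for SBML
    and a plain-text reaction-table dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
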
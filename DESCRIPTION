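Package: nstagecea
Title: Cost-Effectiveness Modelling of Imaging Strategies for Cervical
    Lymph-Node Staging
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decision-analytic cost-effectiveness analysis of diagnostic
    imaging strategies (PET/CT, CT, MRI) for initial cervical lymph-node
    staging of head and neck cancer. A diagnostic-accuracy decision tree
    allocates a clinically N0 cohort across true/false positive/negative
    and metastatic branches; each branch is projected through an
    annual-cycle Markov cohort model (disease-free, recurrence,
    metastatic, dead) over a 10-year horizon with age-dependent
    background mortality, discounting and half-cycle correction.
    Strategies are compared by incremental cost-effectiveness ratio and
    dominance. Includes one-way deterministic (tornado) and
    probabilistic sensitivity analysis with beta/lognormal/uniform
    parameter distributions and cost-effectiveness acceptability curves,
    a microsimulation validation engine, synthetic Gompertz life tables,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
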
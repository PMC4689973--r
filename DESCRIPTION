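Package: osteocea
Title: Markov Cohort Cost-Effectiveness Modelling of Osteoporosis
    Treatments in Elderly Men
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Lifetime cohort Markov model for the cost-effectiveness of
    osteoporosis treatments (denosumab, oral and intravenous
    bisphosphonates, teriparatide) in elderly men, from a US payer
    perspective.  Simulates a cohort over 6-month cycles through a
    hierarchical fracture state space (hip, clinical vertebral, and
    nonhip-nonvertebral fractures with first-year tunnel states),
    with treatment persistence modelled through 6-month discontinuation
    probabilities and a proportional-hazards adjustment for injectable
    therapies, linear post-discontinuation efficacy offset, discounted
    cost/QALY/life-year accounting, incremental cost-effectiveness
    frontier construction with dominance pruning, and deterministic and
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
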
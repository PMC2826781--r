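Package: oncoMarkov
Title: Markov Cohort Cost-Effectiveness Modelling of Adjuvant Chemotherapy
Version: 1.0.0
Authors@R:
    person("oncoMarkov", "Maintainers", email = "oncomarkov@example.org",
           role = c("aut", "cre"))
Description: A four-state Markov cohort model for cost-effectiveness and
    cost-utility analysis of adjuvant chemotherapy regimens in early
    breast cancer. Derives 6-month transition probabilities from 5-year
    arm-level trial outcome counts via a constant-rate conversion,
    runs a discounted two-phase (trial plus extrapolation) cohort
    simulation with full costing of treatment, adverse events,
    granulocyte colony-stimulating factor prophylaxis, metastatic
    chemotherapy and follow-up, and reports incremental cost per
    life-year and per quality-adjusted life-year. Includes one-way
    scenario, bootstrap and primary-prophylaxis sensitivity analyses,
    a synthetic two-arm trial generator for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
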
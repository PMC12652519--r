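Package: bbtnbc
Title: Cost-Effectiveness of Adjunct Beta-Blocker Therapy in Triple-Negative
    Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discounted cohort Markov life-table model evaluating lifelong
    beta-blocker prescription alongside standard care for women diagnosed
    with triple-negative breast cancer (TNBC), from the Australian
    healthcare perspective. Implements transition-probability construction
    from five-year risks, hazard-ratio adjustment on the rate scale,
    half-cycle-corrected accrual of life years, quality-adjusted life years
    (QALYs) and equal-value life years (evLYs), component-wise cost
    accounting, incremental cost-effectiveness ratios with dominance
    classification, one-way (tornado) and probabilistic sensitivity
    analysis with beta/gamma/lognormal parameter distributions, expected
    value of perfect information (EVPI), age-band and disease-stage
    sub-groups, scenario analyses, and a two-proportion trial sample-size
    calculation. A synthetic-data module generates age-indexed all-cause
    mortality, utility norms, breast-cancer incidence and TNBC prevalence
    schedules calibrated to the modelled eligible cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
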
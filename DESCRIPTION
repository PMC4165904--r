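Package: assaycea
Title: Cost-Effectiveness of Gene-Expression Assay-Guided Adjuvant
    Chemotherapy in Early Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A risk-group-stratified Markov cohort model of adjuvant
    chemotherapy decisions guided by a 21-gene recurrence-score assay in
    estrogen-receptor-positive, lymph-node-negative early breast cancer,
    evaluated from the Japanese societal perspective.  Computes lifetime
    discounted costs and quality-adjusted life-years (QALYs) per strategy
    arm, incremental cost-effectiveness ratios, one-way (tornado)
    sensitivity analyses, and a break-even threshold for chemotherapy drug
    cost.  Includes a synthetic decision-impact data generator and an
    individual-level microsimulation oracle for validating the cohort
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
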
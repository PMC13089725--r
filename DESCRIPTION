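Package: smmsurv
Title: Severe Maternal Morbidity Surveillance in Hospital Administrative Claims
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies cases of severe maternal morbidity (the World Health
    Organization's potentially life-threatening conditions) in hospital
    discharge claims from the two Brazilian administrative dialects: the
    public SIH/SUS admission-form (AIH) pair and the private ANS
    consolidated/detailed pair. Ships a versioned codebook of ICD-10 and
    SIGTAP/TUSS procedure code sets, assembles multi-form episodes of care,
    classifies obstetric admissions and the 22 operationalized morbidity
    criteria, and reproduces the surveillance analysis surfaces: criterion
    frequency tables, odds ratios of in-hospital death, and deaths by
    criterion count. Includes a schema-faithful synthetic cohort generator
    with planted prevalence and a logistic death model so the whole pipeline
    is testable without access to the national databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
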
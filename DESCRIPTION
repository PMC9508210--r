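Package: txpathways
Title: Treatment Pathways and Comorbidity Burden in Insurance Claims Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies incident diagnosis cohorts in OMOP-style insurance
    claims tables, computes baseline comorbidity prevalence stratified by age
    and sex, collapses drug dispensings and therapy visits into treatment eras
    with a persistence-gap rule, and sequences each patient's eras into lines
    of therapy (combination, switch and first-instance rules) aggregated into
    a sunburst-ready pathway tree. Ships a configurable synthetic claims-data
    generator so the full pipeline is testable without access to licensed
    claims databases, plus numbered analysis scripts that run the study
    end-to-end on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
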
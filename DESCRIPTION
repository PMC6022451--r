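Package: copdproj
Title: Dynamic Population Model for Projecting COPD Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic multi-state population model that projects the
    prevalence of chronic obstructive pulmonary disease (COPD) in a national
    population aged 45 years and over, from a 2005 baseline to 2025. The
    population is stratified by single-year age, sex, smoking status and
    GOLD grade of airflow limitation (grades 3 and 4 merged), and evolves
    through annual cycles of mortality, smoking-status transitions, incidence,
    GOLD-grade progression, ageing and entrant cohorts. Includes a synthetic
    demography generator calibrated to published aggregates, an iterative
    proportional fitting calibrator that builds the joint baseline prevalence
    table from printed marginals, and a one-way sensitivity-scenario engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
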
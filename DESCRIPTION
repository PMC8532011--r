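Package: carefrag
Title: Care-Fragmentation Analysis of Chronic-Disease Cohorts Under a
    Distance-Parameterized Primary-Care Constraint
Version: 1.0.0
Authors@R:
    person("Ada", "Reyes", email = "ada.reyes@example.org",
           role = c("aut", "cre"))
Description: Rule-based identification of five chronic-disease subgroups
    (asthma, chronic kidney disease, chronic obstructive pulmonary disease,
    type 1 and type 2 diabetes) from relational EHR-style tables, selection
    of patients satisfying a parameterized in-system primary-care-physician
    plus geodesic-distance constraint, and computation of care-fragmentation
    metrics (the share of hospital visits occurring in-system) over
    configurable follow-up windows and a sweep of the distance threshold.
    Includes a WGS-84 Vincenty geodesic solver, an ICD-9/ICD-10 wildcard
    code-pattern engine, a synthetic EHR + all-payer registry generator for
    fully reproducible end-to-end runs, and a pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
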
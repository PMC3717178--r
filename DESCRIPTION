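Package: ncpcost
Title: Costing WHO Nutritional Care Plans for Children Starting Antiretroviral Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies HIV-infected children starting antiretroviral therapy
    into WHO Nutritional Care Plans (NCP-A/B/C) from routine anthropometric and
    clinical data, computes the supplemental energy each plan prescribes,
    costs the resulting feeding courses with locally priced supplement
    products, and compares supplement costs with first-line paediatric ART
    drug costs over a 26-week horizon. Includes LMS z-score computation
    against pluggable growth-reference tables, longitudinal exit-criteria
    evaluation, duration-sensitivity scenario re-costing, and a seeded
    synthetic cohort generator emulating a rural South African treatment
    programme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
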
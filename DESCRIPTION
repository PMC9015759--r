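Package: opencohort
Title: Open Exploration of Integrated Clinical and Environmental Exposure Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, privacy-preserving pipeline for integrating
    patient-level clinical records with spatiotemporal environmental
    exposure surfaces and census socioeconomic attributes, de-identifying
    the result via binning into openly shareable per-study-year feature
    tables, and exploring them with a chi-square association battery with
    Bonferroni correction and contiguous-bin collapsing. Includes a seeded
    synthetic electronic-health-record generator with planted effects, a
    cohort selector driven by configurable diagnosis/medication/procedure
    code sets, a command-line interface, and a minimal HTTP facade for
    cohort-based association queries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
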
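Package: glucotrace
Title: Carbon-Resolved [U-13C]Glucose Tracing Through Glycolysis and the
    TCA Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stable-isotope tracing studies that follow
    [U-13C]glucose through glycolysis and two turns of the TCA cycle in
    brain tissue. Provides a carbon-atom-mapped reaction network with
    positional isotopomer propagation, derivation of labeled scheduled
    multiple-reaction-monitoring (sMRM) transitions from unlabeled Q1/Q3
    base masses and per-analyte fragment rules, percent-enrichment and
    internal-standard concentration quantification from integrated peak
    areas, a statistical battery (two-way type III ANOVA with uncorrected
    Fisher's LSD posttests, Pearson correlation, pooled-variance t tests),
    spectrophotometric enzyme-activity and mitochondrial respirometry
    calculations, and a seeded synthetic-cohort generator that emulates a
    two-group (status epilepticus vs control) animal study for end-to-end
    pipeline validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
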
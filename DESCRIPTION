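Package: trialcoder
Title: Rule-Based Auditing of Sex and Gender Attention in Clinical Trial
    Registrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for screening clinical-trial registry
    dumps (AACT-dialect exports of ClinicalTrials.gov) for COVID-19 relevance
    and for the level of attention each registration pays to participant sex
    and gender.  Implements a case-insensitive, hyphen-blind, plural- and
    wildcard-aware term-matching engine with character-span evidence; a
    field-placement cohort-selection rule with date-window and status
    filters; a hierarchical, mutually exclusive sex/gender attention coding
    scheme (single-sex designs, analysis criterion, other mention,
    recruitment-only, no mention) driven by an editable rule bank with a
    needs-review channel; identification of pharmacological randomized
    controlled trials from design metadata and free text; descriptive
    cross-tabulations with exact half-up percentage rounding; and a
    seed-deterministic synthetic registration generator with ground-truth
    labels and adversarial fixtures so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
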
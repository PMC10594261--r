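Package: caindex
Title: Cumulative Pandemic Adversity Index Construction and Longitudinal
    Mixed-Model Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs a Cumulative Adversity Index (CAI) summarising
    repeated measures of COVID-19-pandemic-related stressor exposure across
    calendar subperiods (weighted items, dependency-group maxima, per-type
    wave maxima, running cumulative scores), scores the QIDS, BAI and
    six-item De Jong Gierveld loneliness instruments, classifies
    pre-pandemic chronicity of psychiatric disorders, and fits linear mixed
    models relating cumulative adversity to period-mean depressive symptoms,
    anxiety symptoms and loneliness. Includes a seeded synthetic cohort
    generator emulating three Dutch psychiatric case-control cohorts, with
    injectable true effects for parameter-recovery simulation, plus a
    reproducible pipeline writing tabular stage outputs and a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
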
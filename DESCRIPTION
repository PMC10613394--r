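Package: cariesCEA
Title: Cost-Effectiveness Analysis of School-Based Dental Caries Prevention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort cost-effectiveness analysis of school-based dental
    caries prevention strategies (fluoride gel application, fissure sealants,
    atraumatic restorative treatment, supervised tooth brushing and dietary
    sugar reduction) against a do-nothing comparator, from a public healthcare
    payer perspective. Provides a four-state annual-cycle cohort engine with
    discounting, deterministic incremental cost-effectiveness ratios with
    dominance ranking and net monetary benefit, probabilistic sensitivity
    analysis with moment-matched gamma (cost) and beta (effectiveness)
    distributions, cost-effectiveness acceptability curves, seeded synthetic
    age schedules with aggregate calibration, and reproducible report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
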
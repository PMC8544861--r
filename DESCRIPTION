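Package: cmlcea
Title: Cost-Effectiveness of Molecular Monitoring in Chronic-Phase CML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A semi-Markov cohort model comparing regular BCR-ABL1 molecular
    monitoring against no monitoring for chronic-phase chronic myeloid
    leukemia from a payer perspective. Provides parametric survival fitting
    to digitized Kaplan-Meier coordinates with AIC-based family selection,
    a compartmental cohort engine with treatment-line sequencing and
    treatment-free remission, cost and QALY accounting with half-cycle
    correction and discounting, incremental cost-effectiveness comparison
    with dominance classification, a scenario library, one-way deterministic
    sensitivity (tornado) analysis, and a synthetic-data module that
    generates digitized-curve and life-table stand-ins for all non-printed
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
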
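Package: soilrisk
Title: Deterministic and Probabilistic Health Risk Assessment for
    Accidental Soil Ingestion of Potentially Toxic Elements
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates human-health risks from accidental (nondietary)
    ingestion of potentially toxic elements (PTEs) in surface soil. Implements
    the standard USEPA-style dose equations (average daily dose, hazard
    quotient, lifetime average daily dose, carcinogenic risk) with risk-zone
    classification, deterministic age/sex receptor scenarios, distribution
    fitting for exposure factors and concentrations (lognormal ingestion rate,
    scaled-beta body weight), Monte Carlo propagation of population risk with
    bootstrap uncertainty of simulation summaries, nonparametric comparison of
    site categories, descriptive statistics with regulation-limit exceedance
    and chromium speciation, and a synthetic concentration-data generator for
    fully reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
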
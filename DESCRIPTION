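Package: pvmix
Title: Mixed-Effects Logistic Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase pharmacovigilance signal detection for spontaneous-report
    databases coded with a MedDRA-style term hierarchy. Phase one screens every
    drug by high-level-term (HLT) pair with Fisher's exact test on case-level
    2x2 contingency tables; phase two fits, for each screened HLT, fixed-effects
    and mixed-effects logistic regression models with a normal random intercept
    per quarterly reporting period, marginalized by Gauss-Hermite quadrature,
    reporting odds ratios with Wald confidence intervals and an AIC comparison
    of the two models. Includes a seeded generator of synthetic spontaneous
    reports with quarter-level heterogeneity, a drug-uptake trend, and
    multi-parent preferred-term coding, so the full pipeline is testable
    without licensed source data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
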
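Package: sepsisperf
Title: Severity Scores and Administrative Data for Sepsis Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate bedside severity scores (SOFA, qSOFA, NEWS,
    SIRS) for predicting 30-day mortality in hospitalised patients with
    infection, and administrative data items (ICD-10 discharge codes,
    blood-culture sampling) as proxy markers for Sepsis-3 sepsis. Implements
    the four scoring instruments with ward-oriented substitution rules
    (SpO2-based SOFA respiratory points, AVPU-to-GCS mapping,
    missing-as-normal), Sepsis-3 phenotyping from timestamped vitals and
    laboratory results around infection onset, diagnostic-accuracy statistics
    with exact confidence intervals, empirical and binary AUROC with DeLong's
    paired test, and a synthetic electronic-health-record cohort generator so
    the full pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils
Suggests:
    pROC,
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
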
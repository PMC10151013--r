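Package: kneebis
Title: Free-Living Knee Bioimpedance Cleaning and Momentary Pain Modelling
Version: 0.1.0
Authors@R: person("kneebis", "maintainers", email = "kneebis@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multi-frequency knee tissue bioimpedance
    collected by a wearable tetrapolar sensing system alongside ecological
    momentary assessment (ESM) self-reports of knee pain. Provides a synthetic
    cohort generator with known ground truth, device-log ingestion with
    battery-discharge session segmentation and self-test verification, an
    ordered decision-tree artifact classifier (session alignment, self-test,
    phase and resistance bands, per-call-period and per-day data-sufficiency
    rules), per-length impedance transforms with per-call-period mean/CV
    reduction and a Spearman redundancy screen, from-scratch random-intercept
    logistic mixed models estimated by adaptive Gauss-Hermite quadrature with
    Wald inference and latent-threshold intraclass correlation, and conditional
    pain-probability curves and per-call-period probability timelines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
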
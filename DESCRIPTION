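Package: trimethr
Title: Methylation ddPCR Quantification, ctDNA Calling and Prognostic
    Analysis for Liquid Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for tumor-agnostic circulating tumor DNA (ctDNA)
    detection from methylation-specific droplet digital PCR (ddPCR) data and
    for downstream prognostic analysis in resectable gastric and
    gastroesophageal junction cancer cohorts. Converts raw droplet amplitudes
    into copies per milliliter plasma via control-derived thresholds and
    Poisson statistics, applies spike-in and bisulfite-conversion quality
    control gates, makes 2-of-3 marker sample calls (the TriMeth rule over
    C9orf50, KCNQ5 and CLIP4), summarises detection across serial timepoints,
    builds recurrence-free and overall survival endpoints with Kaplan-Meier,
    log-rank, Cox and ROC analytics, reproduces the log-rank sample-size
    design with simulation-based power checks, and simulates droplet plates
    and clinical cohorts with known ground truth for end-to-end validation.
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
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
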
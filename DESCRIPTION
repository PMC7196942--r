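Package: casus
Title: Carotid Artery Stenosis Ultrasound Scale Scoring and Prognostic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the carotid artery stenosis ultrasound scale (CASUS):
    per-vessel stenosis scores from duplex ultrasound or angiographic grading,
    patient-level total stenosis scores (TSS, RI-TSS) and global blood flow
    (GBF), the calculated stenosis-score validation statistic, cubic and
    three-segment cubic models of the TSS-GBF relationship, and ROC-based
    prognostic evaluation of stroke endpoints (AUC with Hanley-McNeil standard
    errors, DeLong correlated-AUC comparison, Youden best prediction points).
    Includes a synthetic cohort generator emulating published per-grade flow
    distributions and 180-day event rates so the full pipeline is testable
    without patient data.
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
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
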
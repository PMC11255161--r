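Package: rltdosim
Title: Internal Dosimetry and Simplified-Protocol Evaluation for Lu-177 Radioligand Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for organ-at-risk and tumor-lesion dosimetry in Lu-177
    radioligand therapy (e.g. Lu-177 PSMA ligands for metastatic
    castration-resistant prostate cancer). Implements the MIRD-style
    reference workflow (mono/biexponential time-activity-curve fitting,
    analytic time-integrated activity, sphere-model self-dose), three
    simplified dose estimators (single-time-point TAC rescaling and
    activity-scaled extrapolation from early cycles), Bland-Altman and
    RMSE method agreement, and a calibrated synthetic-cohort generator so
    the full pipeline can be exercised and validated without patient data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
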
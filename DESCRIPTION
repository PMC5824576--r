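Package: pcitriage
Title: Peritoneal Carcinomatosis Index Based Prediction of Suboptimal
    Cytoreduction in Advanced Ovarian Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating peritoneal carcinomatosis index (PCI)
    based prediction of suboptimal cytoreductive surgery (SCS) in advanced
    ovarian cancer. Implements Sugarbaker 13-region PCI scoring and banding,
    surgical outcome classification (complete, optimal, suboptimal
    cytoreduction), the radiologic-laparoscopic unresectability screen, the
    PCI > 20 decision rule per modality (CT, laparoscopy, laparotomy) and
    the combined CT-and-laparoscopy criterion, diagnostic accuracy with
    exact Clopper-Pearson intervals, prevalence-standardized predictive
    values, Youden-index cut-off selection, CUSUM observed-minus-expected
    complication monitoring, and a seeded synthetic cohort generator that
    emulates the statistical structure of a primary-debulking-surgery
    cohort so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
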
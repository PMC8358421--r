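Package: strat4concord
Title: Concordance and Outcome Analysis for RT-qPCR Breast Cancer Biomarker Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating cartridge-based RT-qPCR (delta-Ct) calling of the
    four canonical breast cancer biomarkers (ESR1/ER, PGR/PR, ERBB2/HER2, MKi67/Ki67)
    against immunohistochemistry reference classification. Implements the delta-Ct
    thresholding rules with control-gene validity and indeterminate states, IHC/ISH
    reference classification with the HER2 reflex rule, 2x2 agreement statistics
    (overall/positive/negative percent agreement with Wilson score intervals, Cohen's
    kappa, prespecified performance-target gates), time-to-distant-recurrence survival
    analysis (Kaplan-Meier, Cox proportional hazards with Efron ties), and a synthetic
    cohort generator emulating the marker prevalences, discordance structure and hazard
    structure of a large adjuvant endocrine-therapy trial population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    survival,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
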
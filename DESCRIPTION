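Package: petcorr
Title: Partial-Volume and Uptake-Time Corrections for Quantitative FDG-PET
    Uptake Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative correction chain for 2-[18F]FDG PET uptake metrics
    of liver lesions: an analytic sphere-in-background recovery-coefficient
    (RC) model under Gaussian point-spread blurring with cold-wall correction
    factors, digital image-quality phantom synthesis and measured-RC
    extraction, lesion-level partial-volume correction of mean/peak/max SUV,
    tumor-to-liver and tumor-to-blood (SUR) ratios with uptake-time
    normalization, and downstream two-group separation statistics
    (t tests, Wilcoxon rank-sum, ROC/AUC, logistic regression with optimal
    cutoffs) for mutation-status biomarker analysis, together with a
    synthetic-cohort generator and molecular-pathology annotation parsing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
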
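Package: t1topo
Title: Contrast-Free Tissue Characterization of Acute Myocarditis on Native T1-Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-based detection and quantification of acute myocardial
    injury on native T1-maps, with dark-blood T2-weighted and late gadolinium
    enhancement (LGE) comparators. Implements the 990 ms native T1 criterion
    with a 40 mm^2 minimum contiguous-area filter, remote-ROI based 2-SD
    criteria for T2W edema and LGE, incremental-threshold topographic maps and
    lesion layer/wall pattern classification, AHA 16-segment extent
    quantification, and diagnostic-performance evaluation (sensitivity,
    specificity, ROC/AUC with DeLong comparison, McNemar, Cochran's Q) of
    single and combined criteria. Includes a digital cardiac phantom that
    synthesizes calibrated multiparametric short-axis cohorts with ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    png,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
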
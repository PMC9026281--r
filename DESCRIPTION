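Package: vncaskel
Title: Whole-Skeleton Virtual Non-Calcium Marrow Quantification from
    Dual-Energy CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying bone-marrow infiltration from paired
    dual-energy CT volumes. Computes weighted-average viewing images and
    voxelwise virtual non-calcium (calcium-subtracted) attenuation maps by
    three-material decomposition on the calcium / yellow-marrow / red-marrow
    basis, segments the whole skeleton with a fixed Hounsfield threshold
    followed by morphological Chan-Vese active contours and rule-based
    refinement, extracts whole-skeleton and circular-ROI histogram statistics,
    and runs rank-based cohort statistics (tie-corrected Spearman correlation,
    exact Wilcoxon signed-rank, median/IQR summaries). Includes a seedable
    synthetic dual-energy phantom cohort generator so the full pipeline is
    testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
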
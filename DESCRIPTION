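Package: phyllotex
Title: Whole-Tumor DCE-MRI Texture Analysis for Grading Breast Phyllodes Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a whole-tumor texture-analysis
    workflow for grading breast phyllodes tumors from dynamic
    contrast-enhanced MR images. Provides mu +/- 3 sigma gray-level
    normalization and quantization of a 3D volume of interest, a
    314-feature texture extractor (histogram, gray-level co-occurrence
    matrix, run-length matrix, absolute gradient), a four-stage
    feature-selection cascade ending in backward-stepwise logistic
    regression, an evaluation layer (DeLong AUC machinery,
    Hosmer-Lemeshow calibration, contingency tests, intraclass
    correlation), and a synthetic 3D lesion-phantom generator so the
    whole pipeline is testable without patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
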
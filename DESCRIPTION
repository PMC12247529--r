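Package: fcdseg
Title: Evaluation Pipeline for Focal Cortical Dysplasia Lesion Segmentation on FLAIR MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating automated segmentation of focal cortical
    dysplasia (FCD) type II lesions on 3D FLAIR MRI. Provides NIfTI volume and
    lesion-mask input/output, a preprocessing pipeline (spatial resampling,
    skull stripping, intensity normalization, mask binarization), lesion-focused
    axial slice selection and slab compilation, the Dice and pseudo-Dice metric
    family with mean and moving-average summaries, a 5-fold cross-validation
    harness with pluggable segmenters, fold-level descriptive statistics with
    Student-t confidence intervals and a paired t-test, and a synthetic brain
    phantom generator so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
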
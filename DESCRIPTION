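Package: neuroquant
Title: Atlas-Based Brain Segmentation and Regional PET SUV Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for atlas-based automatic brain segmentation of hybrid
    PET/MR data and regional standardized uptake value (SUV) quantification.
    Implements two complementary pipelines: RATSI (register the atlas
    template to the subject's images, producing a personalized atlas in
    native space) and RSIAT (register the subject's images to the atlas
    template, segmenting spatially normalized PET with the fixed atlas).
    Includes deformation-field estimation, inversion and composition,
    SUV computation with decay correction, segmentation-agreement metrics
    (Dice coefficient, Hausdorff distance, Bland-Altman limits of
    agreement), the group-comparison statistical battery (paired t,
    one-way ANOVA, variance-ratio F, two-sample t), and a synthetic
    PET/MR brain-phantom cohort generator with known ground-truth
    deformations for validation.
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
    withr,
    optparse
Config/testthat/edition: 3
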
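Package: contourprop
Title: Contour Propagation Strategies for MR-Guided Adaptive Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare contour-propagation strategies for daily
    MR-guided radiotherapy of prostate cancer on synthetic pelvic phantom
    cohorts. Implements a trainable 3D U-Net with either a voxel-segmentation
    head (baseline and patient-specific fine-tuned models) or a dense
    displacement field head feeding a differentiable spatial transformer,
    classical benchmarks (rigid contour copying and multi-resolution B-spline
    deformable registration), the training objectives (bending energy,
    multi-scale soft Dice, image similarity, supervised field regression),
    and the geometric and statistical evaluation protocol (Dice similarity
    coefficient, 95th-percentile and average Hausdorff surface distances,
    per-patient-then-cohort aggregation, Kolmogorov-Smirnov normality check
    and paired t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
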
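Package: cttar
Title: CT Texture Analysis of Tumor Heterogeneity with LoG-Filtered
    First-Order Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for CT texture analysis (CTTA) of
    lesion regions of interest: Laplacian-of-Gaussian multiscale filtering
    (fine and coarse scales), first-order intensity-histogram features
    (mean gray intensity, standard deviation, entropy, skewness, kurtosis)
    over masked voxels, Welch two-sample comparison of feature grids with
    Benjamini-Hochberg false-discovery-rate correction, and ROC analysis
    with Youden-optimal cutoffs.  Includes a synthetic phantom cohort
    generator that emulates two-phase contrast CT of renal lesions with
    controllable texture heterogeneity and necrotic cores, so that the
    full pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
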
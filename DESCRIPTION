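Package: mbpattern
Title: Covariance-Pattern Analysis of Longitudinal FDG-PET by PCA and
    Support Vector Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Derives disease-related glucose metabolic brain patterns from
    co-registered FDG-PET volumes by principal component analysis in subject
    space followed by a linear support vector machine (classification or
    epsilon-insensitive regression) solved by sequential minimal
    optimization. The voxel-space pattern p = t(A) w supports expression
    scoring of new scans by inner product, control-referenced Z-values,
    leave-one-out cross-validated accuracy at the pattern-derivation
    timepoint, Wilcoxon rank-sum group comparisons across timepoints, and
    atlas-based regional weighting summaries. Includes a fully synthetic
    longitudinal rat-brain phantom cohort generator with a planted regional
    hyper-/hypometabolism covariance pattern and cylinder-test-like motor
    scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    kernlab,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
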
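Package: gsfusion
Title: Multi-Source Genomic and Multispectral Prediction of Grain Yield
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multi-environment grain-yield prediction in wheat
    breeding trials that fuse genome-wide SNP markers with UAV multispectral
    reflectance. Implements SNP quality control and genomic relationship
    matrices, radiometric calibration and vegetation-index feature
    engineering, per-environment best linear unbiased estimates (BLUEs) under
    alpha-lattice and augmented designs via EM-REML on Henderson's mixed-model
    equations, nine multi-source predictor sets in both concatenated-matrix
    and kernel form, a Bayesian multi-kernel GBLUP fitted by Gibbs sampling,
    a univariate kernel-algorithm partial least squares regression with
    nested component tuning, and two cross-validation protocols (seven-fold
    and leave-one-environment-out). A seeded synthetic-trial generator
    emulating unbalanced partially replicated winter-wheat trials makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    yaml
Config/testthat/edition: 3
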
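Package: methvar
Title: Deterministic and Stochastic Components of Age-Dependent DNA
    Methylation Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for age-dependent variability of DNA
    methylation beta values on Illumina-450k-style matrices. Detects
    age-associated variably methylated positions (aVMPs) from sliding-window
    variance regressions across a cross-sectional and a longitudinal cohort,
    disentangles deterministic from stochastic variability with
    signal-to-noise ratios computed on individual longitudinal trajectories,
    twin pairs and pooled point clouds, infers the scaling law linking
    methylation variance to methylation level via the squared coefficient of
    variation and the Fano factor, and discriminates linear, power-law and
    exponential age trends of the methylation level itself. A synthetic
    cohort generator reproduces the statistical structures the inference
    assumes (heterogeneous diverging trajectories, biased random walks,
    same-sex twin pairs, configurable trend and noise-scaling laws) so that
    every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
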
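Package: tofcow
Title: Quality Metrics for Time-of-Flight Depth Imaging of Cow Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how fur, fur colour, and object velocity degrade
    continuous-wave time-of-flight (TOF) depth imaging of cow-back models.
    Provides a synthetic four-phase TOF scene simulator with a physically
    motivated noise and motion-artifact model, background-subtraction
    segmentation with frame quality tests, boundary/interior region
    partitioning, landmark detection on the lower-back geometry, the
    frame-quality and per-pixel temporal deviation criteria (HQIratio,
    SumDiff, pwStd, RpV), quadratic and Gaussian-exponential least-squares
    fitting with RMSD and R-squared conventions, and Wilcoxon rank-sum tests
    with rank-based eta-squared effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
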
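Package: stripdens
Title: Density Estimation and Survey-Effort Comparison for Strip-Based Benthic Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates benthic animal density from strip-based survey designs
    (quadrat counts, two-observer removal strips, and distance-removal
    transects), propagating uncertainty in counts, cluster size, and detection
    probability by the delta method. Provides maximum-likelihood detection
    models (constant per-observer detection for removal strips; a half-normal
    detection function with imperfect detection on the line for
    distance-removal surveys), a design-based encounter-rate variance,
    chi-squared goodness-of-fit for binned perpendicular distances, a
    required-effort calculator for a target coefficient of variation, and a
    spatially clustered population simulator for evaluating survey designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
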
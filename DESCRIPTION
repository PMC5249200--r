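Package: ctwear
Title: Volumetric Wear Assessment of Polyethylene Acetabular Cups from
    Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies volumetric and mass wear of polyethylene acetabular
    cups from micro computed tomography gray-value volumes: a synthetic cup
    phantom generator with partial-volume blur and noise, parallel-beam
    filtered back-projection at desk scale, ISO-50 surface determination with
    adaptive local sub-voxel refinement, rigid registration with articular
    exclusion, volume differencing with density-based mass conversion, and
    per-vertex wear maps.  Also implements the gravimetric reference workflow
    (soak-control correction, steady-state wear-rate regression, exact
    small-sample Kruskal-Wallis) and the method-agreement analysis used to
    validate CT against gravimetry (linear regression, Bland-Altman limits of
    agreement, Shapiro-Wilk normality, percentage differences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
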
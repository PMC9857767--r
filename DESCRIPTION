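Package: scanmetry
Title: Trueness and Precision of Complete-Arch Implant Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Accuracy assessment of complete-arch implant scans from
    scan-body landmarks. Fits planes and cylinders to labeled contact
    points by orthogonal least squares, intersects the cylinder axis with
    the top plane to obtain scan-body pierce points (centroids), computes
    classified inter-implant distances, and builds trueness and precision
    error tables against a coordinate-measuring-machine style reference.
    Inference follows the field's standard recipe: Box-Cox transformation,
    two-factor linear model (scanner by distance group) with Type-III
    tests, Tukey-adjusted post hoc comparisons and a compact letter
    display. Includes a synthetic study generator (master arch geometry,
    scanner error models with scale bias, stitching drift and point noise,
    STL export) so the whole pipeline is testable without raw scan data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    car,
    emmeans,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
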
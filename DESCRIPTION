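Package: cupwear
Title: Linear Wear of Polyethylene Acetabular Cups from 3D Surface Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Measures linear wear of ultra-high molecular weight polyethylene
    (UHMWPE) acetabular cups from labelled 3D surface point clouds such as
    those digitized on CT isosurfaces or with a coordinate measurement
    machine (CMM). Fits spheres and planes by orthogonal-distance least
    squares with residual-based elimination of metal-artifact outliers,
    constructs cup-anchored orthonormal coordinate frames from the opening
    faces, and reports femoral-head penetration as a wear vector with polar
    and azimuthal angles. Includes a synthetic phantom generator with known
    ground truth for end-to-end validation, and the agreement statistics used
    in method-comparison studies: Bland-Altman limits of agreement, t-based
    bias intervals, ISO 3534-style repeatability and accuracy, and creep
    estimation from soak controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
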
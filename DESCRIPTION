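Package: stack3d
Title: 3D Reconstruction of Serial Histological Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs calibrated 3D voxel models from ordered stacks of 2D
    serial-section images (cryostat histology). Provides background soil and
    glare cleaning by colour-range selection, centroid-based centring,
    slice-to-slice rigid orientation by exhaustive rotation search over an
    intensity-difference metric, radial contour extraction with inter-section
    contour smoothing and proportional interior warping, assembly into a
    physically calibrated voxel volume with tissue and enclosed-cavity volume
    measurement, and isolation of blue-dominant chromogenic (X-Gal type)
    signal. Includes a synthetic phantom generator with exact ground truth
    (applied per-slice transforms, analytic volumes, true tissue and signal
    masks) so every pipeline stage can be validated without real data, plus
    export to MetaImage and NIfTI-1 volume formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
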
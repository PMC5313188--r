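Package: acetabulometry
Title: Three-Dimensional Acetabular Orientation in an Intrinsic Pelvic Frame
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the three-dimensional orientation of the native
    acetabulum from a triangulated pelvic surface and a small set of
    manually picked landmarks. An intrinsic pelvic coordinate system is
    built from the anterior pelvic plane (iteratively refined from the
    anterior superior iliac spines and pubic tubercles), the mid-sagittal
    plane (estimated as the mirror plane of the ASIS regions with an
    iterative closest-point registration), and the transverse pelvic
    plane. A least-squares circle fitted to acetabular rim points yields
    the acetabular axis, which is converted to the anatomic, radiographic,
    and operative definitions of anteversion and inclination. The package
    also ships a voxel segmentation stage (sphere-mask femoral head
    removal, region growing, isosurface extraction, volume-preserving
    smoothing), analytic synthetic pelvis phantoms with exact ground
    truth for validation, simulated-rater reliability studies, and
    intraclass-correlation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
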
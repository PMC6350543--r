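Package: lesionmetry
Title: Ruler-Based 2D and Mesh-Based 3D Skin Lesion Surface Area Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the surface area of skin lesions from photographs.  The 2D
    method detects a flexible checkerboard paper ruler in a single photograph via
    structure-tensor corner analysis, pairs corresponding corners across the ruler,
    extrapolates a local-scale measurement grid over the wound, unwarps each grid
    cell by homography and counts wound pixels to obtain the area in square
    centimetres.  The 3D method reconstructs a sparse point cloud from an image
    sequence by structure from motion, meshes it with a Delaunay triangulation,
    applies Laplacian smoothing and hole filling, calibrates metric scale from a
    reference length and sums the areas of mesh triangles labelled as wound.
    A synthetic phantom generator renders flat and cylindrical scenes with a
    checkerboard ruler and shapes of analytically known area, and builds labelled
    surface meshes with patches of known geodesic area, for validation against
    exact ground truth.  Includes wound/skin segmentation by a random-forest pixel
    classifier with Otsu binarisation and region-of-interest masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    deldir,
    randomForest,
    pracma,
    RANN,
    Matrix,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
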
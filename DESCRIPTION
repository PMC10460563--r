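Package: massbracket
Title: Bracketing Body Volume and Mass of Marine Vertebrates from
    Orthogonal Silhouettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the body volume, surface area, and mass of a marine
    vertebrate with a straight body axis by bracketing it between two 3D
    models built from orthogonal silhouette images. Body cross-sections are
    superellipses whose exponent controls cross-sectional fullness; fins,
    flippers, and the hammerhead cephalofoil are lofted from symmetric NACA
    4-digit foil sections scaled by a square-root thickness envelope.
    Includes sub-pixel silhouette outline extraction, local-regression
    outline smoothing, watertight triangle-mesh construction, volume and
    area measurement by signed-tetrahedron summation, PLY/OBJ/STL mesh
    export, and a geometric validation harness against spheres and prolate
    spheroids of known volume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
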
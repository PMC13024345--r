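Package: patchpath
Title: Conformal Lattice Toolpaths for Robot-Arm Bioprinting on Curved Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates non-planar lattice deposition paths on triangulated
    anatomical surface patches by slicing the mesh with two orthogonal families
    of parallel planes, ordering and resampling the intersection contours into
    a serpentine grid toolpath, and validating the spatial discretization of
    the path against a four-degree-of-freedom articulated-arm kinematic model
    using a circular reference trajectory. Includes STL reading and writing,
    deterministic synthetic surface fixtures (spherical cap, wavy patch, flat
    plate), analytic forward and inverse kinematics for a parallelogram-
    constrained arm with a vertically held tool, and a discretization benchmark
    that reports mean radius and standard deviation of the executed trajectory
    against the arm's repeatability threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
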
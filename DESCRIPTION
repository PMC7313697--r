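Package: markermotion
Title: Color-Marker Detection, Tracking and Joint-Angle Kinematics for RGB-D
    Movement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A low-cost movement-analysis toolkit for marker-based
    rehabilitation recordings. Detects colored geometric markers (six hues,
    four shapes, white borders) in synchronized color and depth frame streams
    using HSV gating, contour features, z-score normalized feature distances
    and Hu-moment shape matching; tracks each marker through occlusion with a
    constant-velocity Kalman filter and a drift gate; back-projects marker
    centers to 3D camera coordinates via the pinhole model and emits
    joint-angle time series. Includes a deterministic synthetic-scene
    generator with full ground truth (marker centers, 3D positions, joint
    angles) for validation, plus evaluation metrics (average joint position
    error in millimetres, mean absolute angle error in degrees) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
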
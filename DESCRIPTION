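Package: berrybias
Title: Grape Maturity Estimation from Depth-Camera Distance Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating post-harvest grape berry maturity from
    time-of-flight and LiDAR depth scans.  Translucent berries appear
    farther from a depth camera than they are because emitted light
    scatters diffusely inside the fruit; the resulting distance bias
    grows as the berry ages.  The package reads and writes point clouds
    (PLY, PCD, XYZ-CSV), back-projects depth images, removes isolated
    speckle with a K-nearest-neighbour distance filter, localizes the
    distorted peak apex in coated (opaque reference) and uncoated scans,
    measures the distance bias in Z-axis and along-ray conventions,
    fits and inverts bias-versus-time maturity curves, and tracks
    percentage weight loss.  A synthetic scan generator reproduces the
    qualitative structure of real scans (rounded coated surface,
    ray-symmetric flattened peak with a fixed base and retreating tip,
    Gaussian depth noise, speckle outliers) so the whole pipeline can
    be exercised and validated without camera hardware.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
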
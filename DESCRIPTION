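Package: btx
Title: Multi-Animal Tracking with Posture, Visual Fields, and Visual Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A batch-oriented toolbox for tracking many individually unmarked
    animals in grayscale video. Segments dark objects against a static
    background model, associates detections across frames with a tree-based
    maximum-probability matcher (with Hungarian and greedy alternatives),
    splits touching individuals by adaptive re-thresholding, estimates 2D
    posture (pixel-corner outlines, elliptic Fourier smoothing, head/tail
    detection and midlines with body thickness), reconstructs per-eye 2D
    visual fields by ray casting with multiple occlusion orders, and corrects
    identities with a uniqueness-guided visual classifier trained on
    automatically selected global segments. Includes a ground-truthed
    synthetic-scene generator, a seekable blob container format, trajectory
    export, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    arrow,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
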
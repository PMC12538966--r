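Package: waveseg
Title: Detection and Segmentation of Two-Phase Tissue Contraction Waves
    from PIV Vector Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and segment recurring two-phase
    ("ventral-then-dorsal") contraction waves in 2D+t and 3D+t microscopy
    recordings of biological tissues. Provides masked particle image
    velocimetry (PIV) on image pairs and sequences, a per-position temporal
    wave segmentation algorithm driven by a sliding-window direction
    similarity score, spatial post-processing of the rasterized phase
    labels (morphological opening, component size and exclusion-region
    filtering), cartographic distortion correction for vector fields
    computed on cylinder projections, surface-shell mask extraction for
    masked 3D PIV, secondary descriptors (expanding-template divergence
    maps, kymographs), and a deterministic synthetic-scene generator with
    ground-truth phase labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
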
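Package: nucmorph
Title: Nuclear Morphometry, Chromatin Condensation and Traction Force
    Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative image analysis of cell nuclei in fluorescence
    microscopy. Segments DAPI-stained nuclei, extracts subpixel boundary
    contours and signed curvature profiles, and calls boundary
    invaginations as contiguous negative-curvature arcs. Scores surface
    wrinkles by Hessian ridge detection on a lamin-like channel, computes
    the chromatin condensation parameter (Sobel edge density within the
    nucleus normalised to cross-sectional area), and measures 3D nuclear
    geometry, shape descriptors, mean intensities, nucleocytoplasmic
    ratios and positive-cell fractions. Includes traction force
    microscopy: drift alignment, particle image velocimetry and
    regularised Fourier-transform traction cytometry on an elastic
    half-space. A synthetic phantom generator with exact ground truth
    (boundary lobes, surface ridges, chromatin texture, bead pairs
    displaced by a known traction field) makes every stage testable
    end-to-end, and per-condition summaries with one-way ANOVA and
    Tukey's HSD reproduce cohort-level statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
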
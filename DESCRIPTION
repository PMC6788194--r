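Package: orrpipe
Title: Intensity-Based Optical Redox Ratio Imaging of 3D Cancer Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of intensity-based optical redox ratio (ORR)
    imaging for 3D cancer cultures and ex vivo tissue slices. Takes raw
    bright-field, NAD(P)H (440 nm band) and FAD (520 nm band) z-stacks,
    collapses them by summation, segments individual spheroids or microtumors
    from the bright-field image with an adaptive local threshold, estimates
    and subtracts per-channel background from the inverse mask, corrects
    spectral bleed-through of NAD(P)H emission into the FAD detection band,
    and computes per-pixel ORR = cFAD / (NAD(P)H + cFAD) maps together with
    per-object redox statistics, heatmaps, stitched slice mosaics and
    normality-gated group comparisons. Includes a synthetic acquisition
    simulator with full ground truth so every stage of the pipeline is
    testable without experimental data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Visualization
RoxygenNote: 7.3.3
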
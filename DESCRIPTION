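Package: scaffoldMRI
Title: Tissue Quantification in Cell-Seeded Porous Scaffolds from Micro-MRI Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-imaging processing for micro-MRI stacks of cell-seeded 3D
    porous scaffolds immersed in liquid. Corrects non-uniform background
    intensity by subtracting a grayscale morphological-opening background
    estimate taken from a scaffold-free reference slice, denoises with a
    disk median filter, segments tissue (bright) and scaffold (dark) by
    global thresholds inside a circular region of interest with the tissue
    threshold calibrated against a bare-scaffold control, quantifies tissue
    as a percentage of available pore volume per slice and per scaffold
    section (with one-way ANOVA and Bonferroni post-tests), builds 4-stage
    projection maps, and reconstructs triangulated tissue/scaffold surface
    models with non-shrinking Taubin smoothing. A synthetic phantom
    generator emulates 0/90 degree woodpile scaffolds with known tissue
    content, bias fields and noise so the whole pipeline is testable
    without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    matrixStats,
    stats,
    graphics,
    tools,
    utils,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
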
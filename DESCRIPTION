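Package: cartbarrier
Title: Quantification of Nanoparticle-Dependent Cartilage Barrier Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for nanoparticle-dependent assessment of
    articular cartilage barrier function. Implements the MRI line-profile
    peak/half-peak distance statistic with pre/post-injection comparison
    (Kruskal-Wallis with Dunn's post-hoc), concentration-threshold detection
    on agarose-well phantoms, two-channel 3-D live/dead cell counting via
    scale-normalised Laplacian blob detection, transwell chemotaxis
    quantification with one-way ANOVA and Holm-Sidak treatment-vs-control
    contrasts (including reconstruction from printed summary statistics),
    replicate-level assay quality control (CV and recovery rules), and
    filtration-loss dose recalibration. A seeded synthetic-data module
    generates calibrated images, fluorescence stacks and plate tables with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
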
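Package: thrombusflow
Title: Multiparameter Analysis of Microfluidic Whole-Blood Thrombus Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and image-based quantification of thrombus formation in
    parallel-plate microfluidic flow chambers. Provides a seeded synthetic-data
    generator for time-resolved, intervention-switchable thrombus kinetics on
    collagen and collagen/tissue-factor microspots, a renderer producing
    four-channel 8-bit microscopy image stacks (brightfield, DiOC6,
    AF568-annexin A5, AF647-fibrin(ogen)) with ground-truth masks, an
    FFT/morphology/threshold segmentation chain, extraction of the seven
    thrombus parameters P1-P7 (surface-area coverage and ordinal morphology,
    contraction and multilayering scores), and replicate-averaged, univariate
    0-10 scaled subtraction heatmaps with paired t-test significance filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    pheatmap,
    png,
    stats,
    tiff,
    utils,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
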
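Package: nanocolumn
Title: Quantification of Trans-Synaptic Nanocolumn Alignment in Expansion
    Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying the nanoscale alignment of
    pre- and post-synaptic protein clusters ("trans-synaptic nanocolumns")
    in roughly 8x-expanded fluorescence microscopy images. Provides Otsu
    segmentation with image-moment shape analysis of synaptic regions, a
    scale-locked (constrained) affine registration of the pre-synaptic onto
    the post-synaptic channel, Pearson cross-correlation and
    orientation-shift statistics, colocalization of a trans-synaptic
    channel, structural and macroscopic expansion-factor estimation, and a
    synthetic multi-channel image generator with known ground truth that
    makes every stage testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
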
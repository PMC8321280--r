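Package: growseg
Title: Automatic Seeded Region-Growing Segmentation of Brain Tumors in MR Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fully automatic brain-tumor segmentation in 2-D MR
    slices by enhanced seeded region growing. The pipeline strips the skull
    with Otsu thresholding and morphological cleanup, ranks 8x8-pixel tile
    mean intensities to initialize seed points automatically, grows a
    candidate region of interest from each seed under an intensity
    tolerance, rescues dark tumor cores by hole filling, and selects the
    best candidate by Dice score against a reference mask. Includes an
    eight-metric evaluation report (accuracy, IoU, Dice, sensitivity,
    specificity, extra fraction, overlap fraction, PSNR), readers and
    writers for PNG/TIFF slices and NIfTI volumes, a synthetic phantom
    generator with known ground truth for end-to-end testing, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    png,
    tiff,
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
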
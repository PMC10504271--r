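Package: efanet
Title: Feature-Alignment Network for Pneumothorax CT Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an efficient encoder-decoder segmentation network for
    pneumothorax on axial chest CT. A multi-scale MBConv encoder with
    squeeze-and-excitation produces a five-level feature pyramid whose feature
    vectors are treated as latent codes at continuous 2-D coordinates; a
    feature-alignment decoder predicts each output pixel by a shared MLP over
    the nearest latent code at every level together with sinusoidally
    position-encoded relative offsets, so masks can be decoded at arbitrary
    resolution without bilinear upsampling. Includes Hounsfield-unit windowing
    and DICOM/NIfTI/PNG input-output, patient-level dataset splitting,
    confusion-matrix segmentation metrics (accuracy, Dice, IoU, sensitivity,
    specificity), a seeded cross-entropy/Adam training loop with parameter and
    FLOP reporting, a synthetic CT phantom generator with crescent-shaped
    pneumothorax lesions, and command-line style workflow entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
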
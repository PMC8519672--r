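Package: liverseg
Title: Adversarial 2.5D VNet Segmentation of Liver CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Liver segmentation for abdominal CT built around a 2.5D VNet
    generator trained adversarially against a Wasserstein critic. Axial
    slices are presented to the network together with their upper and lower
    neighbours; the encoder-decoder uses separable series convolutions
    (1x3x3 intra-slice followed by 3x1x1 inter-slice), chained residual
    pooling on the skip connections, strided-convolution downsampling and
    transposed-convolution upsampling. Training minimises a composite of
    soft Dice loss and a boundary loss driven by the signed Euclidean
    distance map of the ground-truth region, plus an optional Wasserstein
    adversarial term with weight clipping on the critic. Includes NIfTI and
    DICOM-series readers, a deterministic synthetic phantom generator for
    dependency-free testing, overlap metrics (accuracy, Dice), and a small
    command-line interface for phantom generation, training, prediction and
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
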
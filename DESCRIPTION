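Package: voxgan
Title: Three-Round Adversarial Transfer Learning for Volumetric Image
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for classifying 3D gray-matter density maps with a
    three-round learning strategy: a 3D deep convolutional generative
    adversarial network (DCGAN) is pre-trained on unlabeled volumes, its
    residual discriminator is converted into a classifier, and the
    classifier is fine-tuned in two transfer rounds with staged layer
    freezing.  Includes a synthetic brain-phantom cohort generator, NIfTI
    input/output with a deterministic crop/pad/downsample chain, confusion
    and ROC metrics, three ablation harnesses (freeze depth, training
    strategy, sample size), and 3D Grad-CAM saliency maps.  The
    convolutional engine (3D convolution, pooling, batch normalisation,
    Adam) is implemented natively so the whole pipeline runs on a single
    CPU at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    digest,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
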
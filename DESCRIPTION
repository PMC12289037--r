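Package: silogan
Title: Cross-Silo Federated Training of Deep Convolutional GANs for
    Medical Image Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates cross-silo federated learning of deep convolutional
    generative adversarial networks (DCGANs) for grayscale medical image
    synthesis in a single process.  Provides a deterministic image
    preprocessing pipeline (grayscale conversion, CLAHE, gamma correction,
    16-level quantization, rescaling to [-1, 1]), a label-skew non-IID
    partitioner that assigns each severity label to two random clients with
    minimum-size rebalancing, FedAvg aggregation of generator and
    discriminator weights, transfer pretraining on a second imaging domain,
    realism and Frechet-distance evaluation, a four-part privacy-leakage
    audit (membership inference, model inversion, empirical epsilon,
    nearest-neighbour distances) with a composite risk score, and a
    synthetic phantom-image generator (fundus-like and CT-like) so the
    whole framework runs end-to-end without external datasets.  The neural
    network engine (convolutions, transposed convolutions, batch
    normalization, Adam) is implemented on base matrix algebra with sparse
    im2col operators and is fully deterministic under a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    pROC,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
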
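Package: bsda
Title: Bayesian Random Semantic Data Augmentation for Feature-Space Regularization
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feature-space data augmentation for image classifiers. Deep
    features are perturbed along randomly selected semantic directions by
    label-preserving magnitudes drawn from a variationally estimated
    per-sample Gaussian, with an indicator mask that preserves structural
    zeros of post-activation features. Includes the variational magnitude
    estimator and reconstructor, the training harness that plugs the module
    between a feature extractor and a classifier head, reference CNN and MLP
    backbones with hand-written backpropagation, synthetic image and sparse
    feature generators for desk-scale testing, a packed-array (.npz layout)
    reader/writer, evaluation metrics with a multi-seed protocol, exact t-SNE
    feature visualization, and a command-line interface for training,
    ablation, and sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
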
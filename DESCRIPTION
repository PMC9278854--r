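Package: neuriface
Title: Direct Interfacing of Neural Recordings with Deep Convolutional Network Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assesses functional correspondence between neural recordings
    (fMRI voxels, multiunit spike counts) and layers of a deep convolutional
    image classifier by direct interfacing: a learned linear translation
    substitutes recorded activity for a layer's activations and the
    substituted network's task performance scores the correspondence
    (Hand-Till multiclass AUC against labels, Kullback-Leibler divergence
    against image-driven outputs). Includes a self-contained miniature
    VGG-style classifier with exact activation extraction and injection at
    any named layer, three linear translation modes (mean-squared-error,
    end-to-end cross-entropy, PCA-latent target), stratified and
    leave-one-class-out cross-validation, bin-wise temporal interfacing with
    directional Granger-causal comparison of regions, perturbation
    (noise-attenuation) analysis, conventional baselines (MVPA classifiers,
    PLS neural predictivity, pixel-level interfacing), and synthetic
    generators for labeled images, simulated region recordings, and
    two-region feedforward/feedback dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    png,
    nnet,
    class,
    e1071,
    mixOmics,
    withr
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
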
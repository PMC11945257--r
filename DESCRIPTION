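Package: mycosom
Title: Supervised Self-Organizing Map Classification of Macrofungi Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deep-learning-free-of-frameworks implementation of a
    CNN-plus-self-organizing-map (SOM) framework for classifying macrofungi
    species from RGB images. Provides a compact four-block convolutional
    feature extractor trained with Adam and a step learning-rate schedule, a
    from-scratch supervised Kohonen SOM classifier (competitive training,
    Gaussian neighborhood, exponential radius decay, majority-vote neuron
    labeling, best-matching-unit prediction), a sine-activation
    Kolmogorov-Arnold classification head, a two-backbone
    feature-concatenation ensemble head, macro-averaged multi-class
    evaluation metrics including the Gorodkin Matthews correlation
    coefficient and one-vs-rest AUC, and a chi-square procedure for
    statistically comparing two classifiers' confusion matrices. A seeded
    synthetic image generator emulating a seven-species fungal dataset makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
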
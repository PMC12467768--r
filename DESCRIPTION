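Package: tangramcae
Title: Cognitive-Associative Encoding of Tangram Figures and Multidimensional
    Representation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing tangram figures as labelled polygon sets,
    classifying pairwise boundary-contact relations into a 7 x 7 weighted
    adjacency encoding, and analysing the representation dimensions that the
    encoding exposes (animacy, abstraction level, local feature density).
    Includes a synthetic-data module that generates tangram figures with
    controlled relation structure, annotation sets with controlled semantic
    diversity, multichannel evoked-response epochs with planted
    spatiotemporal components, and behavioural trial tables with planted
    effects; a time-resolved multivariate decoding pipeline
    (shrinkage-regularized linear discriminant analysis, temporal
    generalization, cluster-based permutation inference); representational
    similarity analysis with a time-resolved general linear model over
    candidate model dissimilarity matrices; and nonparametric behavioural
    statistics including repetition effects and change-of-mind detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    rpart,
    e1071,
    signal,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
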
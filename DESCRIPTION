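Package: pastnet
Title: Neuroconstructivist Modelling of English Past-Tense Inflection with
    Synthetic Brain Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains constructivist two-pathway neural networks on synthetic
    English-like verb lexicons and analyses the emerging dissociations between
    regular and irregular verbs through synthetic brain imaging. Provides a
    phonological feature encoder for verb forms, a generator for artificial
    verb corpora with Zipfian frequencies and rime-based friend/enemy
    neighbourhoods, an online-trained network with a growing and pruning
    Gaussian hidden layer, per-verb pathway activation measures, and the
    statistical battery used to study the origins of regular/irregular
    dissociations (group tests, correlations, multi-level regressions,
    typicality rankings, complexity-matched subsets, and lesion analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
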
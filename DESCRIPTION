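Package: grwnet
Title: Multiscale Self-Similarity Analysis of Weighted Geometric Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to generate, embed and renormalize weighted networks whose
    topology and link weights are coupled to a latent one-dimensional
    similarity space (the S1/WS1 geometric soft configuration models), with
    application to multiscale weighted brain connectomes. Implements the
    sup-GRW geometric renormalization of weights, weighted observables
    (complementary cumulative distributions, strength-degree relation,
    disparity and its analytic random null), the disparity-filter confidence,
    weak-ties spectra over modular partitions, coordinate-preserving
    weight-reshuffling and coordinate-reshuffling null models, a simplified
    likelihood-based hyperbolic embedding, and a distance-dependent
    consensus-based weighted group representative for multi-subject cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
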
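Package: leadingeight
Title: Indirect Reciprocity with Generous Leading-Eight Social Norms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual-based simulation of indirect reciprocity in the
    donation game with binary private reputations. Implements the
    leading-eight third-order social norms together with two stochastic
    relaxations, assessment generosity (occasionally assigning a good
    reputation where the deterministic norm assigns bad) and action
    generosity (occasionally cooperating where the norm defects);
    image-matrix reputation dynamics under probabilistic observation and
    misperception; exact Markov-chain analysis of tiny populations; and the
    rare-mutation evolutionary competition of a leading-eight norm against
    unconditional cooperation and defection, via pairwise-comparison
    fixation probabilities and the selection-mutation equilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
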
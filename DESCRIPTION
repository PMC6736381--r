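Package: rotasub
Title: Rotamer-Aware Amino Acid Substitution Models for Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and use of empirical protein substitution models on an
    expanded 55-state alphabet in which each residue is paired with its
    side-chain chi1 rotamer configuration. Provides chi1 rotamer assignment
    from atomic coordinates with structure-quality filters, substitution
    counting along neighbor-joining circular tours, count normalization and
    two-stage rate-matrix scaling, Felsenstein pruning log-likelihoods with
    discrete-gamma rate heterogeneity and maximum-likelihood frequencies,
    alignment simulation on phylogenies, cross-state-space model comparison
    via state-corrected AIC and Kullback-Leibler information-loss profiles,
    joint and marginal ancestral reconstruction with a leave-leaves-out
    evaluation protocol, and exchange-pattern statistics including
    bias-corrected Cramer's V and Ramachandran-density overlaps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, ape, bio3d
Suggests: testthat (>= 3.0.0), withr, phangorn, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
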
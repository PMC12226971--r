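Package: cvstates
Title: Collective-Variable Selection and Metastable-State Discovery from Structural Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis toolkit for turning a structurally diverse protein
    ensemble (e.g. AlphaFold2 structures generated with subsampled MSAs) and
    short-trajectory collective-variable (CV) time series into interpretable
    metastable states. Provides an RMSD filter against the highest-confidence
    (pLDDT) reference, enumeration and coefficient-of-variance ranking of
    pairwise-distance features, regular-space clustering to pick diverse seed
    structures, mutual-information-based pruning of redundant CVs (AMINO),
    and a State Predictive Information Bottleneck (SPIB) that learns converged
    state labels and a 2D latent space from time-lagged prediction. Includes
    analytic multi-well Langevin simulators and synthetic structural-ensemble
    generators so the full pipeline is testable without external folding or
    molecular-dynamics engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
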
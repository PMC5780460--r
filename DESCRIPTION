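Package: specmap
Title: Spectral Mapping of Functional from Structural Brain Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a subject's resting-state functional connectivity
    matrix from the structural (tractography-derived) adjacency matrix via a
    weighted polynomial of adjacency powers composed with an orthogonal
    rotation that aligns structural and functional eigenmodes. Provides a
    closed-form per-subject estimator, a rank-constrained variant, and an
    iterative group estimator that fits a common eigenmode basis and shared
    polynomial coefficients across a cohort. Includes the accompanying
    evaluation apparatus (upper-triangle matrix correlation, in/out-of-sample
    time-series splitting, order and rank stability sweeps, multiplicative
    perturbation robustness, null-model swap analyses, cross-subject spectral
    similarity diagnostics) and seeded synthetic generators for structural
    graphs, planted mappings, cohorts and autoregressive BOLD-like series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
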
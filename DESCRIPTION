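Package: jawscape
Title: Theoretical Morphospace and Biomechanical Adaptive Landscapes for Jaw Outlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the evolution of two-dimensional jaw
    silhouettes in a theoretical morphospace. Closed outlines are decomposed
    into elliptic Fourier harmonics, ordinated by principal component
    analysis, and an evenly spaced grid of theoretical shapes is
    reconstructed by inverting the ordination. Each theoretical shape is
    meshed with constant-strain triangles and tested under randomized
    boundary conditions for rotational efficiency and median von Mises
    stress using a plane-stress finite element solver. A bidirectional
    Goldberg Pareto ranking combines the two performance metrics into an
    adaptive landscape over the morphospace, onto which empirical taxa and
    Brownian-motion ancestral reconstructions are projected. Disparity
    (sum of variances, mean pairwise distance) and mean optimality are
    tracked through stratigraphic time bins with bootstrap confidence
    intervals. A synthetic-data module generates jaw-like outlines,
    time-calibrated trees and stratigraphic ranges so the full pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
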
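Package: ssbap
Title: Secondary-Structure-Specific Prediction of Protein Backbone Angles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains and applies secondary-structure-class-specific
    fully-connected neural regressors for the four protein backbone angles
    phi, psi, theta and tau. Residues are routed to a helix-, sheet- or
    coil-specific model according to their predicted secondary structure, so
    each regressor specialises on the angle distribution of one class.
    Includes the sliding-window feature encoding (one-hot 8-state secondary
    structure, PSSM, physicochemical constants, optional HMM profile and
    accessible surface area), a periodic mean-absolute-error loss with a
    step-halving learning-rate schedule, an evaluation suite (periodic MAE,
    Spearman rank correlation, improvement and relative-difference
    percentages, threshold-coverage curves, length-group reports),
    torsion-driven backbone reconstruction from a residue template library
    with RMSD scoring, and a self-contained synthetic-protein generator with
    planted class-conditional angle distributions for end-to-end rehearsal
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
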
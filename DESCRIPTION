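Package: gaussdyn
Title: Multiscale Gaussian Models of Protein Backbone Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents protein backbone dynamics as a hierarchy of Gaussians:
    per-residue anisotropic 3x3 marginal covariances, an NxN scalar
    residue-residue coupling matrix, and an approximate 3Nx3N joint covariance
    reconstructed from the two by a Kronecker heuristic that is symmetric
    positive definite by construction.  Provides extraction of these dynamics
    labels from conformational ensembles (multi-model PDB), an SE(3)-invariant
    learnable predictor with SPD-constrained Cholesky readouts trained under
    the log-Euclidean (log-Frobenius) metric, fast Gaussian ensemble sampling,
    an anisotropic network model (ANM) baseline, evaluation metrics (RMSF
    correlation, root mean 2-Wasserstein distance, symmetric Kullback-Leibler
    variance terms, band-wise coupling correlation, ensemble comparison), and
    a synthetic-data generator with known ground-truth joint covariances so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    MASS
Config/testthat/edition: 3
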
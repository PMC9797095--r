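Package: rnaenm
Title: Sequence-Sensitive Coarse-Grained Normal Mode Analysis of RNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained normal mode analysis of RNA 3D structures using a
    three-bead-per-nucleotide elastic network whose long-range spring constants
    are modulated by all-atom surface-in-contact terms, making the model
    sensitive to sequence and to the effect of point mutations.  Includes two
    anisotropic network model baselines (distance-cutoff and power-dependent),
    per-bead fluctuation descriptors (mean-square fluctuations and vibrational
    entropy signatures), conformational-space comparison metrics (overlap,
    cumulative overlap, RMSIP, NCO, rigid-body-free PCA of structural
    ensembles), sequence clustering utilities, an L1-regularised regression
    pipeline linking dynamics features to functional readouts of sequence
    variants, and deterministic generators of idealized A-form RNA structures
    and synthetic mutational datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    bio3d,
    glmnet,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
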
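Package: fmricontrast
Title: Temporal Contrastive Self-Supervised Pretraining for Task fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for self-supervised pretraining of volumetric brain-state
    decoders on 4-D task fMRI. A run is cut into block-covering clips, each
    clip into (beginning, middle, end) segments, and a 3-D residual encoder
    with a leading temporal convolution is trained so that temporally
    adjacent segments (middle-end) embed closer in contrast space than
    distant ones (beginning-end). Includes NIfTI/BIDS-events I/O, bounding
    box cropping and brain-network (ROI) masking, the contrastive loss and
    pretraining loop, fine-tuning with a linear classifier head, a
    block-design fMRI simulator (double-gamma HRF, AR(1) noise, polynomial
    drift), and subject-level cross-validated evaluation with per-class F1
    and Benjamini-Hochberg corrected significance tests against permutation
    chance. The neural-network engine (3-D convolution, instance
    normalization, Adam) is implemented in C++ via 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
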
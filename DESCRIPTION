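Package: parascint
Title: Quantitative Analysis of Dual-Phase 99mTc-MIBI Parathyroid Scintigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative and volumetric analysis of dual-phase
    99mTc-sestamibi parathyroid imaging in primary hyperparathyroidism.
    Computes planar uptake ratios (early/delayed lesion-to-background and
    lesion-to-thyroid) and the retention index from mirrored regions of
    interest, measures scintigraphic adenoma volume (Svol) by seed-guided
    percent-of-maximum isocontour segmentation of SPECT count volumes, and
    forms the parathormone-to-volume (PTH/Svol) composite. Includes a digital
    phantom generator (ellipsoidal adenoma and thyroid compartments, washout
    kinetics, PSF blur, Poisson counting noise), a Gaussian-copula simulator
    for correlated laboratory and imaging cohorts, and the statistical stage
    of a severity study: normality-gated group comparisons, Spearman
    correlation, ROC analysis with DeLong confidence intervals and
    Youden-index optimal cut-offs, and ICC(2,1) reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    car,
    jsonlite,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
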
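Package: smfdx
Title: Serum Metabolic Fingerprint Diagnostics for Lung Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("SMF", "Maintainers", email = "maintainers@smfdx.example.org",
           role = c("aut", "cre"))
Description: A desk-scale workbench for serum-metabolic-fingerprint (SMF)
    diagnostics built around nanoparticle-assisted LDI mass spectrometry of
    serum. Provides a seeded synthetic-cohort generator (raw spectra with
    planted peaks, Na+/K+ adduct copies, smooth baseline and noise, plus
    clinical covariates), the four-step spectrum preprocessing chain
    (Gaussian smoothing, fixed-width m/z binning, morphological white
    top-hat baseline correction, local-maxima peak detection), residual
    fully-connected neural classifiers on fingerprints alone (Met-NN) and
    fingerprints plus the CEA tumor marker (MP-NN), the Mayo Clinic and
    Veterans Affairs nodule-malignancy equations, a grid-searched
    random-forest tri-modal fusion stage (MPI-RF), and an evaluation suite
    (ROC/AUC with DeLong confidence intervals and tests, Youden thresholds,
    operating-point rates, permutation overfitting tests, and Hanley-McNeil
    AUC power analysis).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
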
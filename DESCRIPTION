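Package: strokecbf
Title: Perfusion and Tissue-Damage Mapping in Chronic Stroke Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to characterize cerebral blood flow (CBF) inside chronic
    stroke lesions from pseudo-continuous arterial spin labeling (pCASL)
    MRI together with tissue-damage maps computed as a normalized T2w/T1w
    ratio (TIGR). Provides motion-aware control/label pair censoring,
    single-compartment CBF quantification under three spatial-smoothing
    placements (none, before subtraction in native space, after
    quantification in template space), sphere/air region-of-interest
    quality metrics (SNR, coefficient of variation, grey-white
    contrast-to-noise), per-subject CBF-versus-damage regression with
    Bonferroni assessment, a group factorial model with demographic and
    stroke-related factors and their cross-terms, and a synthetic
    stroke-brain phantom generator with known ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
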
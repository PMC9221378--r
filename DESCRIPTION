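Package: octraman
Title: Multimodal OCT Texture and Raman Band Analysis for Tumor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for classifying skin and subcutaneous tumor samples from
    two optical modalities: scanning-window speckle-texture statistics of
    optical coherence tomography (OCT) B-scans, and band-averaged intensities
    of fingerprint-region Raman spectra. Provides bespoke tissue masking of
    B-scans (threshold, interior-void filling, saturation-artifact column
    removal), 15x15 sliding-window feature extraction, iterative polynomial
    autofluorescence baseline correction and band integration for Raman
    spectra, linear discriminant classification with leave-one-out
    cross-validation, Mann-Whitney significance matrices, and a synthetic
    data generator that emulates the texture and spectral contrasts of skin,
    lipoma, mast cell tumor, and soft tissue sarcoma samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    jsonlite
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
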
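Package: specfuse
Title: Low-Level Fusion of NIR and MIR Fibre-Probe Spectra with PLS-DA
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for binary tissue classification from paired
    near-infrared (NIR) reflectance and mid-infrared (MIR) attenuated-total-
    reflection spectra. Implements block-wise spectral preprocessing (standard
    normal variate, Savitzky-Golay derivatives, series-wide min-max scaling),
    low-level data fusion by block concatenation, NIPALS partial least-squares
    discriminant analysis with Variable Importance in Projection (VIP) scores,
    leave-one-out and Monte Carlo cross-validation with strict fold isolation,
    ROC-based model ranking, and an experiment driver comparing single-modality
    versus fused and global versus per-organ models. Includes a synthetic
    paired-cohort generator (Gaussian bands, patient random effects, baseline
    drift, multiplicative scatter) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
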
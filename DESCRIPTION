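Package: ramancell
Title: Label-Free Single-Cell Raman Spectroscopy Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis of label-free live single-cell Raman
    spectra of cancer cell lines. Provides a synthetic-spectrum generator with
    per-cell-line band profiles, the preprocessing chain used for single-cell
    Raman data (despiking, silicon wavenumber calibration, scaled background
    subtraction, Savitzky-Golay smoothing, asymmetric least-squares baseline
    correction, truncation and excision, Amide-I normalization and standard
    normal variate), Gaussian band decomposition of the Amide I/III and
    CH-stretch regions, filtered band correlation analysis, a cross-validated
    classifier suite (PCA+LDA, decision trees, boosted small-tree ensembles,
    linear SVM) and partial least squares regression against ordinal disease
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    signal,
    minpack.lm,
    rpart,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mixOmics,
    withr,
    yaml
Config/testthat/edition: 3
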
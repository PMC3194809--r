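Package: peakconcord
Title: Reproducibility of Peak and Biomarker Detection Across SELDI-TOF MS
    Pre-Processing Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the choice of mass-spectrometry
    pre-processing algorithm affects the reproducibility of peak and
    differentially-expressed (DE) peak detection. Implements three
    average-spectrum-dependent pre-processing presets (Savitzky-Golay /
    moving-average baseline / TIC with FFT alignment; continuous-wavelet
    ridge-line detection with linear-interpolation baseline and median-AUC
    normalisation; undecimated-wavelet denoising with monotone-minimum
    baseline), shift-window peak matching, Student's t-tests with simple and
    fold-change-stratified Benjamini-Hochberg FDR control, percentage-of-
    overlap (PO) and normalised PO consistency scores against permutation
    nulls, and a synthetic spectrum simulator with known ground truth for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
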
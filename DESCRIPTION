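Package: ftirserum
Title: Quality Control, Preprocessing and Nested Classification for Dried-Serum FTIR Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end chemometrics toolkit for small dried-serum
    Fourier-transform infrared (FTIR) cohorts: per-spectrum quality-control
    metrics (amide-I signal-to-noise, robust spike counting, cosine coherence
    against the cohort median, baseline-area fraction), composable
    preprocessing variants (rubber-band baseline correction, vector
    normalization, Savitzky-Golay derivatives, atmospheric-region masking,
    spectral-window restriction), unsupervised structure diagnostics
    (cosine distances, Ward-type clustering, classical MDS, t-SNE), and a
    leakage-safe supervised core combining symmetric-uncertainty feature
    selection (FCBF or univariate ranking) with Gaussian Naive Bayes under
    leave-one-out cross-validation, label-permutation validity testing and
    quantile-binned reliability with Brier scoring. A synthetic-cohort
    generator with full ground-truth sidecars makes every stage testable
    without access to clinical spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    jsonlite
Config/testthat/edition: 3
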
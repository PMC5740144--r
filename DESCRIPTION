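Package: pmiftir
Title: Postmortem Interval Estimation from ATR-FTIR Biofluid Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for estimating the postmortem interval (PMI)
    from attenuated-total-reflectance Fourier-transform infrared (ATR-FTIR)
    spectra of biofluids such as pericardial fluid. Implements spectral
    ingestion and replicate/group averaging, standard normal variate (SNV)
    and Savitzky-Golay second-derivative preprocessing, generalized
    two-dimensional correlation spectroscopy (synchronous and asynchronous
    maps via the Hilbert-Noda transform) with automated sequential-order
    calls under Noda's rules, partial least squares (PLS/NIPALS) regression
    with variable-importance-in-projection (VIP) scores, nu-support-vector
    regression with radial-basis-function kernel and two-dimensional grid
    search, animal-wise k-fold cross-validation, external validation, and
    permutation testing with the intercept criterion. A synthetic-spectra
    generator emulating a time-course biofluid study with known ground truth
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
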
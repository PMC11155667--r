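Package: peakfitr
Title: Declarative Peak Fitting for Spectroscopic Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonlinear least-squares deconvolution of spectra into
    composite lineshape models (Gaussian, Lorentzian, pseudo-Voigt,
    Voigt, step and background functions), driven by declarative model
    files in JSON, YAML or TOML. Supports parameter bounds, user-supplied
    arithmetic constraint expressions, simultaneous fitting of several
    spectra with shared peak energies, a six-table fit-statistics suite
    (descriptive statistics, chi-square/AIC/BIC, Pearson correlation of
    components, regression metrics), profile-likelihood confidence
    intervals, and a tamper-evident single-file TOML lock report with a
    content-hash identifier. A seeded generator of XAS-like synthetic
    spectra makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    digest,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
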
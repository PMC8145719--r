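Package: nmrvoigt
Title: Untargeted Peak Fitting of 1D NMR Spectra with Pseudo-Voigt Lineshapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Untargeted processing of one-dimensional proton NMR spectra for
    metabolomics: per-spectrum peak picking with noise filtering, bounded
    nonlinear least-squares fitting of pseudo-Voigt lineshapes, analytic peak
    integration, alignment of peak integrals to a reference spectrum, and
    frequency plus signal-to-noise feature filtering. Includes the two
    conventional comparison methods (full-spectra intensity matrices and
    equidistant trapezoidal binning), probabilistic quotient normalization,
    unit-variance-scaled principal component analysis, a standard-addition
    error-estimation protocol, and a deterministic simulator of urine-like
    spectra with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
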
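Package: pegsolve
Title: Planning and Analysis of Automated PEG-Precipitation Protein Solubility Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the automated polyethylene-glycol (PEG) precipitation
    assay used to rank proteins by relative solubility. Plans per-well
    titration recipes and liquid-handler worklists from assay design
    parameters, parses multi-well absorbance spectra (220-700 nm), applies
    Savitzky-Golay smoothing and sigma-based spectral quality control,
    computes soluble protein concentrations from blanked A280 corrected at
    A340 (and turbidity from blanked A500), and fits the precipitation
    sigmoid to estimate PEG1/2 with bootstrap confidence intervals, curve
    onset, and log-extrapolated apparent solubility. Includes a synthetic
    plate simulator with known ground truth so the whole pipeline can be
    validated without instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    minpack.lm,
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
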
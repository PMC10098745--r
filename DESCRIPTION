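Package: coaxperm
Title: Coaxial-Cell Complex Permittivity Extraction for Liver Tissue Dielectric Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns two-port S-parameter sweeps measured in a coaxial
    transmission-line cell into complex permittivity spectra and two-group
    contrasts, for ex-vivo tissue dielectric spectroscopy in the 100 MHz to
    2 GHz band. Implements reference-plane de-embedding against short-circuit
    and empty-cell sweeps, Nicolson-Ross closed-form extraction with
    reflection-root and logarithm-branch selection, Debye/Cole-Cole tissue
    relaxation models, group spectral summaries with repeatability bands and
    unpaired t-tests, Touchstone (.s2p) input/output, and a synthetic-cohort
    generator that produces physically consistent measurement sets for a
    healthy versus fatty (hepatic steatosis) liver contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'coaxperm-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'tissue_models.R'
    'forward_model.R'
    'deembed.R'
    'nrw.R'
    'cohort_stats.R'
    'synthetic_data.R'
    'io_touchstone.R'
    'io_csv.R'
    'config_io.R'
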
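Package: milkbarrier
Title: Analysis of In Vitro Blood-Milk Barrier Transport Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bidirectional transport experiments on
    epithelial cell monolayers grown on permeable (transwell) supports, with
    defaults matching a primary human mammary epithelial cell model of the
    blood-milk barrier. Covers barrier-integrity quality control
    (blank-corrected transepithelial electrical resistance, sodium-fluorescein
    leakage against a fluorescence calibration curve), apparent-permeability
    estimation from receiver-compartment time series with
    sampling-with-replacement dilution correction, censoring at the limit of
    quantification, iterative linearity trimming, directional medians and
    efflux (polarity) ratios, delta-Ct relative expression profiling of
    transporter gene panels against a multi-gene reference panel, population
    doubling time, and an exact two-compartment transwell transport simulator
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
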
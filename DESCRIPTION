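Package: diskfret
Title: Lifetime-Based FRET Analysis for Coupled Chromophore Disk Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing excitation-energy transfer between covalently
    coupled protein-disk chromophore arrays such as circularly permuted
    tobacco mosaic virus (cpTMV) double disks bearing donor and acceptor dye
    rings. Provides synthetic time-correlated single photon counting (TCSPC)
    decay generation (multiexponential decay convolved with a Gaussian
    instrument response plus counting noise), mono- and biexponential
    reconvolution lifetime fitting with asymptotic standard errors and reduced
    chi-squared, lifetime-based Foerster resonance energy transfer (FRET)
    rate and efficiency inference, and an idealised ring-array geometry model
    that apportions transfer across donor-acceptor pathways by the inverse
    sixth power of distance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
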
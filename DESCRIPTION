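Package: fermspec
Title: Chemometric Quantification of Fermentation Substrates and
    Metabolites from FTIR Spectra
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for at-line monitoring of microbial fermentations by
    Fourier transform infrared (FTIR) spectroscopy.  Simulates realistic
    attenuated total reflection (ATR) and dry-film high-throughput (HTS)
    spectra of fermentation supernatants from a Beer-Lambert band model,
    implements the standard spectral preprocessing chain (region
    selection, baseline offset correction, Savitzky-Golay smoothing and
    derivatives, technical-replicate averaging, SNV and EMSC
    normalisation), and provides from-scratch latent-variable calibration
    (PCA and NIPALS PLS1 regression) with segmented cross-validation and
    independent-test validation for quantifying glucose and citric acid
    in growth media.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
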
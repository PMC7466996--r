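Package: burdenlab
Title: Transcription-Initiation Limits and the Protein-Burden Expression Signature
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models transcription initiation as a stochastic attempt process
    gated by a promoter-clearance dead time, and provides the analysis
    machinery for protein-burden expression studies in budding yeast:
    synthetic burden-library and mutant-compendium generation,
    growth-rate expression responses (E_g), expression-dependent bias
    (delta) with TATA stratification, competition-assay fitness and
    scaled epistasis, ChIP-style coverage processing with background
    subtraction and plasmid occupancy, two-species spike-in calibration
    of total mRNA per cell, and a critical-cell-size growth model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
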
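Package: famespec
Title: FAME Quantification and FTIR Chemometrics for Bacterial Lipid Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for characterizing temperature-induced lipid and
    whole-cell biochemical changes in bacteria. Converts GC-FID peak tables of
    fatty acid methyl esters (FAMEs) into per-acid weights and total lipid
    content using a C19:0 internal standard and relative response factors;
    parses fatty-acid labels into structural descriptors and classifies them by
    chain length, branching, unsaturation, geometry, hydroxylation and ring
    content; preprocesses FTIR absorbance spectra (Savitzky-Golay filtering,
    region cutting, extended multiplicative signal correction on second
    derivatives); estimates relative lipid and phosphorus content from band
    ratios (1742/1656 and 1083/1656 cm-1); and explores the data with PCA and
    grouped Pearson correlations. A seeded synthetic strain-panel generator
    with a known ground-truth ledger makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
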
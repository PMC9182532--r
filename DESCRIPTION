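Package: coinspec
Title: Confocal Coincidence Spectroscopy and Protease-Protection Core Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of two-colour confocal coincidence spectroscopy (CCS)
    records of amyloid assemblies: simulation of dual-channel photon time
    traces from diffusing labelled species with known ground truth, robust
    burst detection in 1-ms binned photon traces, the directional colourQ
    coincidence statistic (RedQ/GreenQ) for quantifying heteromeric
    assembly, and photon-counting histograms of burst intensities.  A
    companion module maps limited-proteolysis LC-MS peptide reads onto a
    parent protein sequence, computes per-residue read prevalence, and
    delineates the protease-protected amyloid core around a seed tetrad.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
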
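Package: nmrts
Title: De Novo Molecule Identification from 1H NMR Line Spectra by Monte
    Carlo Tree Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate molecular structures from a proton NMR
    line spectrum by Monte Carlo tree search over SMILES strings. The
    search is guided by a next-symbol policy model trained on a SMILES
    corpus, scored by the first Wasserstein distance between line spectra
    combined with a carbon/hydrogen atom-count penalty, and accelerated
    by preloading the search tree with database molecules ranked by
    spectral similarity. Spectrum prediction is a pluggable oracle: a
    deterministic surrogate shift predictor is bundled for desk-scale
    runs, and a file-based exchange adapter supports external
    quantum-chemistry backends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
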
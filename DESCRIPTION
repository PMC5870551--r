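Package: contactr
Title: Residue-Residue Contact Predictions: Formats, Evaluation and Plots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for working with protein residue-residue contact
    predictions. Provides a hierarchical data model (contact, contact map,
    contact file; sequence, sequence file), read/write/convert support for
    seventeen contact-prediction text dialects and four sequence/alignment
    formats, alignment quality statistics (effective sequence count,
    per-column depth, per-sequence coverage, coverage trimming), precision
    evaluation of predictions against contacts extracted from protein
    structures, publication figures (contact map, sequence coverage,
    stepwise precision curves), a command-line interface, and deterministic
    synthetic fixture generators for chains, predictions and alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
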
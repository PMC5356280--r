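Package: nmrstar
Title: Lossless Parsing, Writing and JSON Conversion of BMRB NMR-STAR Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete parsing stack for the NMR-STAR flat-file format used
    by the Biological Magnetic Resonance Data Bank (BMRB), versions 2.1 and
    3.1. Provides a STAR tokenizer robust to the multiline edge cases that
    break naive parsers, an order-preserving nested data model
    (entry/saveframe/loop), a writer with automatic value quoting, lossless
    bidirectional conversion to JSON, streaming ingestion from files,
    directories, zip/tar archives and URLs, extraction and visualization of
    assigned chemical shifts organized by residue, a deterministic synthetic
    fixture generator with ground-truth manifests, and a command-line
    interface for bulk conversion and chemical-shift viewing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
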
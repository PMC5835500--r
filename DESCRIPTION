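Package: glycoctx
Title: Sequence-Context Mining of N-Glycosylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterises the local sequence environment of N-glycosylated
    asparagines. Extracts fixed-width context windows around annotated
    acceptor sites, encodes flanking residues into charge/polarity classes,
    estimates significantly preferred residue-position pairs with exact
    binomial tests, mines maximal association patterns of preferred items
    over a grid of support thresholds, and validates mined rules by
    conformity percentages against prediction-derived peptide sets and
    literature sequon tables. Includes a synthetic sequence generator with
    planted context items for end-to-end calibration, and a single-command
    pipeline runner producing a reproducible result bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
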
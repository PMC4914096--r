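Package: restaple
Title: Design of Custom DNA-Origami Scaffolds from Reusable Staple Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing DNA-origami scaffold sequences that fold from a
    small set of reusable staple sequences. Reads and writes caDNAno version-2
    JSON designs, traces scaffold and staple routing, randomly segments an
    unbroken staple routing into staples grouped into k sequence classes,
    derives the forced-complementary custom scaffold sequence, scores scaffold
    repetitiveness as the fraction of nucleotides covered by any w-base window
    occurring more than once, and ranks a seeded library of candidate layouts
    to select the least repetitive design. Includes synthetic helix-bundle
    fixture generators, restriction-motif screening, and FASTA/CSV/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
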
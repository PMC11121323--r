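Package: bescreen
Title: In Silico Screening of Pathogenic SNVs for CRISPR Base-Editing Amenability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies single-nucleotide variants by base-editor class and
    targeted strand, enumerates protospacer placements with degenerate-IUPAC
    PAM matching for adenine base editor (ABE8e) constructs on a junction-aware
    mini-transcript model, and predicts bystander edits inside the editing
    window with coding (silent/missense) and canonical-splice consequences.
    Includes reconstructed CRB1 case fixtures and a seeded generator of
    synthetic transcripts with planted, ground-truthed variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
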
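Package: nestedTE
Title: Detection and Evolutionary Analysis of Nested Transposable Element
    Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying cooperative transposable-element (TE)
    insertions in genome annotation data. Parses UCSC-style repeat
    (rmsk) and gene-model (refGene) tables, reassembles fragmented
    repeats via their linkage identifiers, and detects combined
    host/guest TE configurations (a younger element nested inside an
    older, fragmented one) together with the sequence hallmarks of
    target-primed reverse transcription: target-site duplications and
    poly-A tails. Downstream analyses include genomic-context
    classification against gene models, enumeration of TE-derived
    exonization candidates from antisense splice dinucleotides with
    open-reading-frame and peptide-effect reports, position-weight-
    matrix branch-point scoring with a distance prior and
    polypyrimidine-tract term, and dating of insertions on a calibrated
    species tree from presence/absence profiles under a single-gain
    model. A synthetic-genome generator with a planted-truth manifest
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
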
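Package: rnaformats
Title: Parse, Translate, Abstract and Summarize RNA Secondary Structures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with RNA secondary structures encoded as arc
    diagrams. Reads and writes the common plain-text encodings (BPSEQ, CT,
    extended dot-bracket with or without sequence, arc-annotated sequence,
    FASTA) and the XML-based RNAML dialect produced by tools such as RNAView,
    enforcing a format compatibility matrix for translations in single-file
    and batch mode. Pseudoknotted structures are rendered in extended
    dot-bracket via first-come-first-served page assignment. Three arc-diagram
    abstractions (core, core plus, shape) reduce structures to their
    topological skeletons for motif census work, and per-molecule statistics
    (nucleotide and base-pair class counts) support dataset-level summaries.
    Includes a synthetic-structure generator for download-free testing and a
    command-line interface for batch pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
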
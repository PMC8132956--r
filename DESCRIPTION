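Package: orthovote
Title: Consensus 1:1 Ortholog Calling by k-of-n Tool Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalizes the native outputs of six orthology-inference tools
    (OrthoFinder, ProteinOrtho, InParanoid, OMA, SwiftOrtho, FastOrtho) to
    gene-level orthogroups via RefSeq-to-Entrez identifier mapping built from
    GTF and GPFF annotation records, calls 1:1 orthologs for a species pair by
    k-of-n exact-orthogroup agreement across tools, laterally infers orthologs
    between non-anchor species through an anchor species, and converts
    RNA-seq expression units (TPM, FPKM, transcripts per embryo). Ships a
    seeded synthetic-fixture generator that renders planted ortholog maps
    into all six tool dialects so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
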
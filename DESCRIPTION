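Package: entorip
Title: Comparative Genomic Screens for RIP, Domain Enrichment and
    Orthogroup Occupancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed dinucleotide scans for repeat-induced point
    mutation (RIP) with the composite index and a genome-level percent-RIPped
    summary; cross-genome protein-domain count matrices with exclusive
    set intersections, pairwise Fisher exact enrichment (Bonferroni
    corrected) and fold-versus-median calls; rule-based classification of
    protein domain architectures (circadian clock, RNA interference and
    RID methyltransferase candidates); orthogroup occupancy and
    species-specificity analysis with an expression-support filter; and
    seeded simulators for genomes with RIP-mutated repeat families,
    domain annotation tables with planted enrichments, and orthogroup
    tables with planted occupancy structure, so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
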
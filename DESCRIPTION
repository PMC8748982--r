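Package: astroreact
Title: Reactive Astrocyte Translatome Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for characterising astrocyte responses to
    chronic neurodegenerative pathology from TRAP-seq translatome count
    data. Implements FPKM normalisation, a simplified negative-binomial
    Wald test for differential expression, rank-based derivation of
    stimulus-specific and pan-reactive astrocyte gene sets from
    two-stimulus fold-change tables, 2x2 Fisher enrichment with Woolf
    confidence intervals and log-odds-ratio comparisons, a multi-cutoff
    GWAS risk-gene enrichment sweep, cross-model core-signature and
    cross-species comparisons, quantification of transcriptomic rescue in
    factorial genotype designs, allele-fraction scoring of reads spanning
    a two-allele locus, and horizontal-bar behavioural scoring. A
    synthetic-data module generates every input with planted ground truth
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
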
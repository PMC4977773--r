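Package: irescout
Title: Genome-Wide Discovery of Iron-Responsive Element Stem-Loops in
    Gene-Flanking UTR Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts iron-responsive element (IRE) stem-loops in fixed-length
    genomic flanks standing in for unannotated 5' and 3' UTRs. Combines an
    IUPAC anchor prescreen for the apical CAGUGH loop with a combinatorial
    hairpin geometry checker (C8 bulge, five-pair upper stem, lower stem),
    a Nussinov maximum base-pairing engine with an exhaustive enumeration
    oracle, High/Medium/Low call scoring and the associated retention filter.
    Downstream layers scan known UTR regulatory elements (polyadenylation
    signals, upstream ORFs, AU-rich elements, miRNA seed boxes), test their
    enrichment, discover over-represented motifs by ZOOPS expectation
    maximisation against a k-order Markov background, validate 5' calls
    against transcription start sites, and categorise cross-species ortholog
    support. A seeded synthetic-genome generator with a planted-feature truth
    table provides end-to-end validation for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
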